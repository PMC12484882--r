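# Synthetic-data generators: single-stereocenter chiral molecules with
# exact R/S ground truth, spring-network molecules with toy-potential
# equilibria, and partially annotated multi-task label suites. All
# generators are pure functions of (parameters, seed).

#' Assign an R/S label from the signed volume at a stereocenter
#'
#' Substituent priorities are the atomic numbers of the atoms bonded to
#' the center (ties broken by atom index). With `s1, s2, s3` the positions
#' of the three highest-priority substituents and `c` the center, the
#' label is `"R"` when `det[s1 - c, s2 - c, s3 - c] > 0` and `"S"` when it
#' is negative — a simplified Cahn–Ingold–Prelog convention whose mirror
#' behavior (reflection flips the label) matches the full rules.
#'
#' @param conf a [conformation()].
#' @param center_index index of the stereocenter atom.
#' @param substituents indices of the four substituent atoms.
#' @return list with `label` ("R"/"S") and `volume` (the signed
#'   determinant, in cubic Angstrom).
#' @export
chiral_label <- function(conf, center_index, substituents) {
  stopifnot(length(substituents) == 4L)
  z <- conf$elements[substituents]
  ord <- order(-z, substituents)
  top3 <- substituents[ord[1:3]]
  rel <- conf$positions[top3, , drop = FALSE] -
    matrix(conf$positions[center_index, ], 3L, 3L, byrow = TRUE)
  vol <- det(t(rel))
  list(label = if (vol > 0) "R" else "S", volume = vol)
}

# Fixed asymmetric stereocenter core: center carbon at the origin and four
# substituent sites in priority order (rows 2-5 = priorities 1-4). The
# arrangement was chosen (once, by a design search over random cores) to
# keep the chirality-aware torsion angles around the center well away
# from zero, so that handedness leaves a robust signature in the torsion
# features under coordinate jitter.
chiral_core <- rbind(c(0, 0, 0),
                     c(-0.1144, 0.3921, 1.5015),
                     c(-1.0073, -0.1233, 1.0386),
                     c(1.0777, -0.7496, 0.7865),
                     c(1.0916, 0.3699, -0.8920))

# Deterministic scaffold for a given heavy-atom count: carbon chains grown
# round-robin outward from the substituent sites, with a fixed internal
# seed so each size has one canonical geometry.
chiral_scaffold <- function(n_heavy) {
  with_seed(90210L + n_heavy, {
    positions <- chiral_core
    tips <- 2:5
    for (e in seq_len(n_heavy - 5L)) {
      s <- ((e - 1L) %% 4L) + 1L
      anchor <- tips[s]
      out_dir <- positions[anchor, ] - positions[1L, ]
      out_dir <- out_dir / sqrt(sum(out_dir^2))
      for (try_ in 1:50) {
        d <- out_dir + stats::rnorm(3L, sd = 0.25)
        d <- d / sqrt(sum(d^2))
        cand <- positions[anchor, ] + 1.5 * d
        if (min(row_norms(positions -
                          matrix(cand, nrow(positions), 3L,
                                 byrow = TRUE))) > 1.0) break
      }
      positions <- rbind(positions, cand)
      tips[s] <- nrow(positions)
    }
    positions
  })
}

# Mean torsion angle over the valid edges incident to the stereocenter —
# the reflection-odd statistic whose sign separates the two classes.
stereocenter_psi <- function(conf, center_index = 1L) {
  g <- build_graph(conf)
  tors <- torsion_angles(chirality_vectors(g), g)
  ce <- (g$edges[, 1L] == center_index | g$edges[, 2L] == center_index) &
    tors$valid
  if (!any(ce)) return(0)
  mean(tors$psi[ce])
}

# Scaffolds are canonicalized so that the R orientation has a positive
# stereocenter torsion statistic; computed once per size and cached.
scaffold_cache <- new.env(parent = emptyenv())

canonical_scaffold <- function(n_heavy) {
  key <- as.character(n_heavy)
  pos <- scaffold_cache[[key]]
  if (is.null(pos)) {
    pos <- chiral_scaffold(n_heavy)
    # placeholder substituents in decreasing priority along rows 2-5
    conf <- conformation(c(6L, 17L, 16L, 9L, 8L, rep(6L, n_heavy - 5L))[
      seq_len(n_heavy)], pos)
    lab <- chiral_label(conf, 1L, 2:5)$label
    stat <- stereocenter_psi(conf)
    # align label and torsion-sign conventions: swapping the two highest
    # priority sites flips the label but leaves the geometry (and hence
    # the torsion statistic) unchanged
    if ((lab == "R") != (stat > 0)) pos[c(2L, 3L), ] <- pos[c(3L, 2L), ]
    scaffold_cache[[key]] <- pos
  }
  pos
}

#' Generate a balanced dataset of single-stereocenter chiral molecules
#'
#' Each molecule has one tetrahedral stereocenter: a carbon bonded to four
#' substituents with distinct atomic numbers (drawn from N, O, F, S, Cl),
#' plus carbon chains for 5-12 heavy atoms in total. Geometries are
#' jittered copies of fixed per-size scaffolds whose handedness,
#' substituent priority order, and torsion signature are mutually
#' consistent; molecules destined for the S class are reflected, and every
#' molecule receives a random rotation and translation. Labels are
#' recomputed from the final geometry through [chiral_label()]. Samples
#' with a near-planar center (signed volume <= 0.05), clashing atoms, or
#' an ambiguous torsion signature (stereocenter torsion statistic
#' inconsistent with the label, which jitter occasionally produces) are
#' rejected and redrawn, so the dataset is exactly separable by the sign
#' of the mean stereocenter torsion angle. Classes are balanced to within
#' one molecule.
#'
#' @param n number of molecules.
#' @param seed integer seed.
#' @param n_heavy_range inclusive range of heavy-atom counts.
#' @param jitter coordinate noise (Angstrom) around the scaffold.
#' @return list of `chiral_molecule` objects: `conformation`, `label`,
#'   `volume`, `center_index` (= 1), `substituents` (= 2:5).
#' @export
make_chiral_dataset <- function(n, seed = 1L, n_heavy_range = c(5L, 12L),
                                jitter = 0.04) {
  with_seed(seed, {
    want_s <- sample(rep(c(FALSE, TRUE), length.out = n))
    lapply(seq_len(n), function(k) {
      repeat {
        n_heavy <- sample(n_heavy_range[1L]:n_heavy_range[2L], 1L)
        scaf <- canonical_scaffold(n_heavy)
        subs_z <- sort(sample(c(7L, 8L, 9L, 16L, 17L), 4L),
                       decreasing = TRUE)
        elements <- c(6L, subs_z, rep(6L, n_heavy - 5L))
        pos <- scaf + matrix(stats::rnorm(length(scaf), sd = jitter),
                             nrow(scaf), 3L)
        if (want_s[k]) pos[, 1L] <- -pos[, 1L]
        conf0 <- conformation(elements, pos)
        lab <- chiral_label(conf0, 1L, 2:5)
        if (abs(lab$volume) <= 0.05) next
        if (min(stats::dist(pos)) <= 0.8) next
        if ((lab$label == "R") != (stereocenter_psi(conf0) > 0)) next
        rot <- random_rotation()
        pos <- pos %*% t(rot) +
          matrix(stats::rnorm(3L, sd = 2), nrow(pos), 3L, byrow = TRUE)
        conf <- conformation(elements, pos,
                             mol_id = sprintf("chiral%05d", k))
        lab <- chiral_label(conf, 1L, 2:5)
        return(structure(list(conformation = conf, label = lab$label,
                              volume = lab$volume, center_index = 1L,
                              substituents = 2:5),
                         class = "chiral_molecule"))
      }
    })
  })
}

#' Mirror image of a chiral molecule
#'
#' Reflects the conformation and recomputes the label, which always flips.
#'
#' @param mol a `chiral_molecule` from [make_chiral_dataset()].
#' @return the enantiomeric `chiral_molecule`.
#' @export
mirror_molecule <- function(mol) {
  conf <- reflect_conformation(mol$conformation)
  lab <- chiral_label(conf, mol$center_index, mol$substituents)
  structure(list(conformation = conf, label = lab$label,
                 volume = lab$volume, center_index = mol$center_index,
                 substituents = mol$substituents),
            class = "chiral_molecule")
}

# ---- toy potential and equilibrium conformers ---------------------------

#' Toy molecular potential: harmonic bonds + soft-core repulsion
#'
#' `E = sum_bonds k/2 (r - r0)^2 + sum_{nonbonded pairs} c (s / r)^12`.
#' A transparent stand-in for a classical force field: it has well-defined
#' local minima, analytic gradients, and rises under any perturbation of
#' an equilibrium geometry.
#'
#' @param positions `n x 3` coordinates.
#' @param bonds `b x 2` integer matrix of bonded pairs.
#' @param k spring constant (default 4).
#' @param r0 bond rest length (Angstrom, default 1.5).
#' @param c_rep repulsion prefactor (default 0.05).
#' @param sigma repulsion length scale (default 1.1).
#' @return list with `energy` and `gradient` (`n x 3`).
#' @export
toy_potential <- function(positions, bonds, k = 4, r0 = 1.5,
                          c_rep = 0.05, sigma = 1.1) {
  n <- nrow(positions)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  bkey <- pmin(bonds[, 1L], bonds[, 2L]) +
    n * pmax(bonds[, 1L], bonds[, 2L])
  is_bond <- (pairs[, 1L] + n * pairs[, 2L]) %in% bkey
  dv <- positions[pairs[, 1L], , drop = FALSE] -
    positions[pairs[, 2L], , drop = FALSE]
  r <- row_norms(dv)
  coef <- numeric(length(r))
  energy <- sum(0.5 * k * (r[is_bond] - r0)^2) +
    sum(c_rep * (sigma / r[!is_bond])^12)
  # d(energy)/dr, divided by r to scale the difference vectors
  coef[is_bond] <- k * (r[is_bond] - r0) / r[is_bond]
  coef[!is_bond] <- -12 * c_rep * sigma^12 / r[!is_bond]^14
  gpair <- dv * coef
  grad <- matrix(0, n, 3L)
  gi <- rowsum(gpair, pairs[, 1L], reorder = TRUE)
  grad[as.integer(rownames(gi)), ] <- gi
  gj <- rowsum(gpair, pairs[, 2L], reorder = TRUE)
  grad[as.integer(rownames(gj)), ] <-
    grad[as.integer(rownames(gj)), , drop = FALSE] - gj
  list(energy = energy, gradient = grad)
}

# Random connected bond graph: a random spanning tree plus a few extras.
random_bond_graph <- function(n) {
  bonds <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L), 0L))
  n_extra <- sample(0:max(1L, n %/% 4L), 1L)
  for (e in seq_len(n_extra)) {
    cand <- sample.int(n, 2L)
    if (abs(cand[1L] - cand[2L]) > 0L) bonds <- rbind(bonds, sort(cand))
  }
  unique(bonds)
}

#' Generate spring-network molecules at their equilibrium geometry
#'
#' Each molecule is a random connected bond graph whose geometry is
#' minimized under [toy_potential()] to a gradient max-norm below `gtol`.
#' The minimized coordinates are stored both as `positions` and
#' `equilibrium_positions`, ready for [perturb_conformation()].
#'
#' @param n_molecules number of molecules.
#' @param n_atoms_range inclusive range of atom counts.
#' @param seed integer seed.
#' @param gtol gradient tolerance at the returned geometry.
#' @return list of `toy_molecule` objects: `conformation`, `bonds`, and
#'   `energy` (the equilibrium toy energy).
#' @export
make_equilibrium_set <- function(n_molecules, n_atoms_range = c(6L, 10L),
                                 seed = 1L, gtol = 1e-4) {
  with_seed(seed, {
    lapply(seq_len(n_molecules), function(mi) {
      n <- sample(n_atoms_range[1L]:n_atoms_range[2L], 1L)
      bonds <- random_bond_graph(n)
      # grow a rough initial layout along the tree
      pos <- matrix(0, n, 3L)
      for (i in 2:n) {
        parent <- bonds[bonds[, 1L] == i | bonds[, 2L] == i, , drop = FALSE]
        parent <- setdiff(as.vector(parent[1L, ]), i)[1L]
        d <- stats::rnorm(3L); d <- d / sqrt(sum(d^2))
        pos[i, ] <- pos[parent, ] + 1.5 * d
      }
      obj <- function(x) toy_potential(matrix(x, n, 3L), bonds)$energy
      gr <- function(x) as.vector(toy_potential(matrix(x, n, 3L),
                                                bonds)$gradient)
      x <- as.vector(pos)
      for (round_ in 1:8) {
        opt <- stats::optim(x, obj, gr, method = "L-BFGS-B",
                            control = list(maxit = 500L, factr = 10))
        x <- opt$par
        if (max(abs(gr(x))) < gtol) break
      }
      eq <- matrix(x, n, 3L)
      elements <- sample(c(6L, 6L, 7L, 8L), n, replace = TRUE)
      structure(list(
        conformation = conformation(elements, eq,
                                    equilibrium_positions = eq,
                                    perturbation = matrix(0, n, 3L),
                                    mol_id = sprintf("spring%04d", mi)),
        bonds = bonds,
        energy = toy_potential(eq, bonds)$energy),
        class = "toy_molecule")
    })
  })
}

# ---- multi-task suites --------------------------------------------------

radius_of_gyration <- function(conf) {
  p <- conf$positions
  ctr <- colMeans(p)
  sqrt(mean(rowSums((p - matrix(ctr, nrow(p), 3L, byrow = TRUE))^2)))
}

heteroatom_fraction <- function(conf) mean(conf$elements != 6L)

#' Generate a partially annotated multi-task label suite
#'
#' Emulates the hypergraph structure of real property panels: each task
#' labels only a subset of the molecules. Labels are deterministic
#' functions of geometry and composition (radius of gyration, heteroatom
#' fraction, atom count), cycled over regression and classification
#' types; tasks 1 and 3 are affine images of the same radius-of-gyration
#' latent, so their labels are strongly correlated on the molecules both
#' annotate. Task
#' statistics (positive ratio or mean/std) are computed from the realized
#' labeled subsets.
#'
#' @param n_molecules number of molecules.
#' @param n_tasks number of tasks (>= 2).
#' @param coverage labeled fraction per task (scalar or vector).
#' @param seed integer seed.
#' @return list of class `synthetic_task_suite` with `data` (a
#'   [mol_dataset()]), `coverage` (realized per task) and `molecules`
#'   (the underlying `toy_molecule` list).
#' @export
make_multitask_suite <- function(n_molecules, n_tasks = 4L, coverage = 0.5,
                                 seed = 1L) {
  stopifnot(n_tasks >= 2L)
  coverage <- rep_len(coverage, n_tasks)
  mols <- make_equilibrium_set(n_molecules, seed = derive_seed(seed, 5L))
  confs <- lapply(mols, `[[`, "conformation")
  names(confs) <- vapply(confs, `[[`, "", "mol_id")
  rg <- vapply(confs, radius_of_gyration, 0)
  het <- vapply(confs, heteroatom_fraction, 0)
  nat <- vapply(confs, n_atoms, 0L)
  latents <- list(rg, het, 1.8 * rg - 0.5, as.numeric(nat), rg + het)
  with_seed(derive_seed(seed, 6L), {
    tasks <- list(); labels <- list()
    for (t_ in seq_len(n_tasks)) {
      lat <- latents[[((t_ - 1L) %% length(latents)) + 1L]]
      sel <- sort(sample.int(n_molecules, round(coverage[t_] * n_molecules)))
      vals <- lat[sel]
      if (t_ %% 2L == 1L) {       # odd tasks: regression
        tasks[[t_]] <- task_meta(t_, "regression", group = "physicochemical",
                                 target_mean = mean(vals),
                                 target_std = max(stats::sd(vals), 1e-6),
                                 name = paste0("reg", t_))
      } else {                    # even tasks: classification by median cut
        thr <- stats::median(lat)
        vals <- as.numeric(vals > thr)
        if (all(vals == vals[1L])) vals[1L] <- 1 - vals[1L]
        tasks[[t_]] <- task_meta(t_, "classification", group = "toxicity",
                                 positive_ratio = mean(vals),
                                 name = paste0("cls", t_))
      }
      labels[[t_]] <- data.frame(mol_id = names(confs)[sel], task_id = t_,
                                 value = vals)
    }
    structure(list(
      data = mol_dataset(confs, tasks, do.call(rbind, labels)),
      coverage = vapply(labels, nrow, 0L) / n_molecules,
      molecules = mols),
      class = "synthetic_task_suite")
  })
}

#' Embed a SMILES string as a 3D conformation
#'
#' Delegates to the Open Babel command-line tool (distance-geometry
#' embedding plus force-field cleanup via `--gen3d`). Open Babel is an
#' optional runtime dependency; when it is not installed this function
#' fails with an informative error and nothing else in the package
#' depends on it.
#'
#' @param smiles a SMILES string.
#' @return a [conformation()].
#' @export
smiles_to_conformer <- function(smiles) {
  obabel <- getOption("moltask.obabel", Sys.which("obabel"))
  if (!nzchar(obabel) || !file.exists(obabel))
    stop("smiles_to_conformer requires the Open Babel 'obabel' executable; ",
         "install Open Babel or set options(moltask.obabel = ...)")
  out <- tempfile(fileext = ".xyz")
  on.exit(unlink(out))
  status <- suppressWarnings(
    system2(obabel, c(paste0("-:", shQuote(smiles)), "-oxyz", "--gen3d",
                      "-O", out),
            stdout = FALSE, stderr = FALSE))
  confs <- if (file.exists(out) && file.size(out) > 0) read_xyz(out)
           else list()
  if (status != 0 || length(confs) == 0L)
    stop("could not embed SMILES string: ", smiles)
  conf <- confs[[1L]]
  conf$mol_id <- smiles
  conf
}
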