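#' Construct a catalysis dataset
#'
#' Bundles the species table (ids + SMILES), the per-functional adsorption
#' energy table and, optionally, a functional-ensemble energy matrix
#' (e.g. the 2000-member BEEF-vdW ensemble) for one catalyst surface.
#'
#' @param species Data frame with columns `species_id` and `smiles`.
#' @param energies Numeric matrix, species x functionals (eV), with
#'   column names naming the functionals; row order matches `species`.
#' @param ensemble Optional numeric matrix, species x ensemble members (eV).
#' @param surface Surface label, e.g. `"Pt(111)"`.
#' @return An object of class `catalysis_dataset`.
#' @export
catalysis_dataset <- function(species, energies, ensemble = NULL,
                              surface = "Pt(111)") {
  stopifnot(is.data.frame(species),
            all(c("species_id", "smiles") %in% names(species)))
  species$species_id <- as.character(species$species_id)
  energies <- as.matrix(energies)
  if (nrow(energies) != nrow(species))
    stop("energy table must have one row per species", call. = FALSE)
  if (is.null(colnames(energies)) || any(!nzchar(colnames(energies))))
    stop("energy table columns must be named after functionals", call. = FALSE)
  if (anyDuplicated(colnames(energies)))
    stop("duplicated functional labels in energy table", call. = FALSE)
  dup <- unique(species$species_id[duplicated(species$species_id)])
  if (length(dup) > 0L)
    stop(sprintf("duplicated species id(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  if (anyNA(energies)) {
    idx <- which(is.na(energies), arr.ind = TRUE)
    offenders <- sprintf("%s/%s", species$species_id[idx[, 1]],
                         colnames(energies)[idx[, 2]])
    stop(sprintf("missing energy cell(s): %s", paste(offenders, collapse = ", ")),
         call. = FALSE)
  }
  parse_fail <- vapply(species$smiles, function(s)
    inherits(tryCatch(parse_smiles(s), error = identity), "error"), logical(1))
  if (any(parse_fail))
    stop(sprintf("unparseable SMILES for species: %s",
                 paste(species$species_id[parse_fail], collapse = ", ")),
         call. = FALSE)
  if (!is.null(ensemble)) {
    ensemble <- as.matrix(ensemble)
    if (nrow(ensemble) != nrow(species))
      stop("ensemble matrix must have one row per species", call. = FALSE)
    if (anyNA(ensemble)) stop("missing values in ensemble matrix", call. = FALSE)
    rownames(ensemble) <- species$species_id
  }
  rownames(energies) <- species$species_id
  structure(list(species = species[, c("species_id", "smiles")],
                 energies = energies,
                 ensemble = ensemble,
                 surface = surface),
            class = "catalysis_dataset")
}

#' @export
print.catalysis_dataset <- function(x, ...) {
  cat(sprintf("catalysis_dataset: %d species on %s\n", nrow(x$species), x$surface))
  cat(sprintf("  functionals: %s\n", paste(colnames(x$energies), collapse = ", ")))
  if (!is.null(x$ensemble))
    cat(sprintf("  ensemble: %d members\n", ncol(x$ensemble)))
  invisible(x)
}

#' Functionals of a dataset
#' @param dataset A `catalysis_dataset`.
#' @return Character vector of functional labels.
#' @export
functionals <- function(dataset) colnames(dataset$energies)

#' Read a species/energy table from disk
#'
#' Expects a CSV with columns `species_id`, `smiles` and one `E_<functional>`
#' column per functional (adsorption energies in eV), plus an optional
#' companion CSV with `species_id` followed by the ensemble members.
#'
#' @param path Path to the dataset CSV.
#' @param ensemble_path Optional path to the ensemble CSV.
#' @param surface Surface label.
#' @return A `catalysis_dataset`.
#' @export
load_dataset <- function(path, ensemble_path = NULL, surface = "Pt(111)") {
  if (!file.exists(path)) stop(sprintf("dataset file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("species_id", "smiles")
  if (!all(need %in% names(df)))
    stop(sprintf("dataset load error: %s must have columns species_id, smiles", path),
         call. = FALSE)
  ecols <- grep("^E_", names(df), value = TRUE)
  if (length(ecols) == 0L)
    stop(sprintf("dataset load error: %s has no E_<functional> columns", path),
         call. = FALSE)
  energies <- as.matrix(df[, ecols, drop = FALSE])
  colnames(energies) <- sub("^E_", "", ecols)
  ensemble <- NULL
  if (!is.null(ensemble_path)) {
    ens <- utils::read.csv(ensemble_path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!"species_id" %in% names(ens))
      stop(sprintf("ensemble load error: %s missing species_id", ensemble_path),
           call. = FALSE)
    ord <- match(as.character(df$species_id), as.character(ens$species_id))
    if (anyNA(ord))
      stop(sprintf("ensemble load error: species %s absent from %s",
                   paste(df$species_id[is.na(ord)], collapse = ", "), ensemble_path),
           call. = FALSE)
    ensemble <- as.matrix(ens[ord, setdiff(names(ens), "species_id"), drop = FALSE])
  }
  catalysis_dataset(df[, need], energies, ensemble = ensemble, surface = surface)
}

#' Write a dataset to disk
#'
#' Inverse of [load_dataset()]: writes `species_id`, `smiles` and
#' `E_<functional>` columns, and optionally the ensemble matrix.
#'
#' @param dataset A `catalysis_dataset`.
#' @param path Output CSV path.
#' @param ensemble_path Optional output path for the ensemble matrix.
#' @return `dataset`, invisibly.
#' @export
write_dataset <- function(dataset, path, ensemble_path = NULL) {
  df <- dataset$species
  e <- as.data.frame(dataset$energies)
  names(e) <- paste0("E_", colnames(dataset$energies))
  utils::write.csv(cbind(df, e), path, row.names = FALSE)
  if (!is.null(ensemble_path) && !is.null(dataset$ensemble)) {
    ens <- as.data.frame(dataset$ensemble)
    utils::write.csv(cbind(species_id = dataset$species$species_id, ens),
                     ensemble_path, row.names = FALSE)
  }
  invisible(dataset)
}

#' Summary statistics of a dataset
#'
#' @param dataset A `catalysis_dataset`.
#' @return List with `n_species`, `mean_abs_energy` (named, eV, per
#'   functional) and `ensemble_members` (0 if absent).
#' @export
dataset_statistics <- function(dataset) {
  list(n_species = nrow(dataset$species),
       mean_abs_energy = colMeans(abs(dataset$energies)),
       ensemble_members = if (is.null(dataset$ensemble)) 0L else ncol(dataset$ensemble))
}

#' Enumerate C/H surface intermediates up to a carbon count
#'
#' Generates every connected graph of at most `max_carbons` carbons with
#' bond orders 1--3 and per-carbon free valence 0--3 (hydrogens fill the
#' rest of the valence), deduplicated by graph isomorphism and serialised
#' as canonical SMILES. This is the propane-dehydrogenation intermediate
#' family for `max_carbons = 3`.
#'
#' @param max_carbons Between 1 and 3.
#' @return Sorted character vector of canonical SMILES.
#' @examples
#' enumerate_intermediates(1)  # "C" "[CH]" "[CH2]" "[CH3]"
#' @export
enumerate_intermediates <- function(max_carbons) {
  stopifnot(max_carbons >= 1L, max_carbons <= 3L)
  graphs <- list()
  add <- function(h, bonds) {
    n <- length(h)
    bd <- if (is.null(bonds)) data.frame(from = integer(0), to = integer(0), order = integer(0))
          else bonds
    bs <- rep(0L, n)
    for (b in seq_len(nrow(bd))) {
      bs[bd$from[b]] <- bs[bd$from[b]] + bd$order[b]
      bs[bd$to[b]] <- bs[bd$to[b]] + bd$order[b]
    }
    fv <- 4L - h - bs
    if (any(fv < 0L | fv > 3L)) return(invisible(NULL))
    g <- structure(list(atoms = data.frame(element = rep("C", n),
                                           hydrogen_count = as.integer(h),
                                           free_valence = as.integer(fv)),
                        bonds = bd),
                   class = "molecular_graph")
    for (old in graphs) if (graph_isomorphic(old, g)) return(invisible(NULL))
    graphs[[length(graphs) + 1L]] <<- g
    invisible(NULL)
  }

  for (h in 1:4) add(h, NULL)
  if (max_carbons >= 2L) {
    for (b in 1:3) for (h1 in 0:(4L - b)) for (h2 in 0:(4L - b))
      add(c(h1, h2), data.frame(from = 1L, to = 2L, order = b))
  }
  if (max_carbons >= 3L) {
    # chains 1-2-3
    for (b12 in 1:3) for (b23 in 1:3) {
      if (b12 + b23 > 4L) next
      for (h1 in 0:(4L - b12)) for (h2 in 0:(4L - b12 - b23)) for (h3 in 0:(4L - b23))
        add(c(h1, h2, h3),
            data.frame(from = c(1L, 2L), to = c(2L, 3L), order = c(b12, b23)))
    }
    # 3-rings
    for (b12 in 1:3) for (b13 in 1:3) for (b23 in 1:3) {
      if (b12 + b13 > 4L || b12 + b23 > 4L || b13 + b23 > 4L) next
      for (h1 in 0:(4L - b12 - b13)) for (h2 in 0:(4L - b12 - b23)) for (h3 in 0:(4L - b13 - b23))
        add(c(h1, h2, h3),
            data.frame(from = c(1L, 1L, 2L), to = c(2L, 3L, 3L),
                       order = c(b12, b13, b23)))
    }
  }
  c_sort(vapply(graphs, canonical_smiles, character(1)))
}

#' Configuration for the synthetic multi-functional generator
#'
#' The generator emulates the statistical structure the invariant-
#' representation method assumes: a shared latent adsorption-energy
#' function of the molecular graph (linear in the 24-length flat
#' fingerprint), plus per-functional linear distortions ("functional
#' idiosyncrasies") and observation noise, plus a low-diversity ensemble
#' of pseudo-functionals around the latent function.
#'
#' Default latent coefficients combine a free-valence term (about -1 eV
#' per dangling bond, the order of linear-scaling slopes for CHx fragments
#' on transition-metal surfaces) with per-bond terms of 1-2 eV for
#' unsaturated and mixed-hybridisation carbon-carbon backbone bonds (the
#' di-sigma/bridge-bound motifs whose surface rehybridisation carries
#' large specific energy contributions). These backbone-bond motifs are
#' sparse across the intermediate family, so the energetically decisive
#' structure is deliberately not aligned with the directions of largest
#' fingerprint variance - the situation an invariant-representation
#' method must handle. Functional scales/offsets are of the order of
#' typical inter-functional shifts (a few percent in slope, one to two
#' tenths of an eV in offset).
#'
#' @param n_species Number of species drawn from [enumerate_intermediates()].
#' @param functionals Labels for the simulated functionals.
#' @param latent_coefficients Named vector over [flat_schema()] (eV/count);
#'   missing entries are 0.
#' @param functional_scale,functional_offset Per-functional slope and
#'   offset applied to the latent energy (recycled to the number of
#'   functionals).
#' @param distortion_scale Std dev (eV) of each functional's random linear
#'   distortion coefficients over the 24 features.
#' @param noise_sd Observation noise std dev (eV).
#' @param ensemble_members Number of pseudo-functional ensemble columns.
#' @param ensemble_spread Std dev (eV) of the ensemble distortion
#'   coefficients; smaller than `distortion_scale` makes the ensemble less
#'   diverse than the functionals.
#' @param ensemble_offset_sd Std dev (eV) of the per-member constant offset.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration including this seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species = 40L,
                             functionals = c("PBE-D3", "RPBE", "BEEF-vdW", "SCAN+rVV10"),
                             latent_coefficients = c(
                               "FV" = -0.9, "C=C" = -0.5, "C#C" = -1.8,
                               "C1-C2" = -1.4, "C1-C3" = -1.8, "C2-C3" = -1.6,
                               "C0-C3" = -1.2, "C1-C1" = -0.8,
                               "H" = -0.04, "C" = 0.12),
                             functional_scale = c(1.00, 0.94, 1.05, 0.97),
                             functional_offset = c(0.00, 0.15, -0.12, 0.22),
                             distortion_scale = 0.1,
                             noise_sd = 0.05,
                             ensemble_members = 2000L,
                             ensemble_spread = 0.03,
                             ensemble_offset_sd = 0.02,
                             seed = 1L) {
  stopifnot(n_species >= 4L, noise_sd >= 0, distortion_scale >= 0,
            ensemble_spread >= 0, length(functionals) >= 1L)
  if (anyDuplicated(functionals))
    stop("functional labels must be distinct", call. = FALSE)
  structure(list(n_species = as.integer(n_species),
                 functionals = functionals,
                 latent_coefficients = latent_coefficients,
                 functional_scale = rep_len(functional_scale, length(functionals)),
                 functional_offset = rep_len(functional_offset, length(functionals)),
                 distortion_scale = distortion_scale,
                 noise_sd = noise_sd,
                 ensemble_members = as.integer(ensemble_members),
                 ensemble_spread = ensemble_spread,
                 ensemble_offset_sd = ensemble_offset_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic multi-functional dataset
#'
#' Draws species from the enumerated intermediate family and builds, for
#' each functional f, energies `E_f(s) = a_f g(s) + b_f + u_f . x(s) + eps`
#' where `g(s)` is the latent energy (latent coefficients dotted with the
#' flat fingerprint `x(s)`), `u_f` is a random distortion vector of scale
#' `distortion_scale` and `eps ~ N(0, noise_sd)`. Ensemble member k gets
#' `E_k(s) = g(s) + v_k . x(s) + b_k` with `v_k` of scale
#' `ensemble_spread`. Identical configurations (including the seed)
#' reproduce identical datasets.
#'
#' @param config A [synthetic_config()].
#' @return A `catalysis_dataset` with attribute `latent` (the latent
#'   energies g) and `config`.
#' @export
generate_synthetic_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  pool <- enumerate_intermediates(3L)
  if (config$n_species > length(pool))
    stop(sprintf("n_species = %d exceeds the %d enumerable species",
                 config$n_species, length(pool)), call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  smiles <- c_sort(sample(pool, config$n_species))
  ids <- sprintf("s%02d", seq_along(smiles))
  X <- fingerprint_matrix(stats::setNames(smiles, ids), kind = "flat24")
  sch <- flat_schema()
  beta <- stats::setNames(numeric(length(sch)), sch)
  beta[names(config$latent_coefficients)] <- config$latent_coefficients
  g <- drop(X %*% beta)

  nf <- length(config$functionals)
  E <- matrix(NA_real_, nrow(X), nf, dimnames = list(ids, config$functionals))
  for (f in seq_len(nf)) {
    u <- stats::rnorm(length(sch), 0, config$distortion_scale)
    eps <- stats::rnorm(nrow(X), 0, config$noise_sd)
    E[, f] <- config$functional_scale[f] * g + config$functional_offset[f] +
      drop(X %*% u) + eps
  }
  ensemble <- NULL
  if (config$ensemble_members > 0L) {
    ensemble <- matrix(NA_real_, nrow(X), config$ensemble_members,
                       dimnames = list(ids, sprintf("ens%04d", seq_len(config$ensemble_members))))
    for (k in seq_len(config$ensemble_members)) {
      v <- stats::rnorm(length(sch), 0, config$ensemble_spread)
      bk <- stats::rnorm(1, 0, config$ensemble_offset_sd)
      ensemble[, k] <- g + drop(X %*% v) + bk
    }
  }
  ds <- catalysis_dataset(data.frame(species_id = ids, smiles = smiles,
                                     stringsAsFactors = FALSE),
                          E, ensemble = ensemble, surface = "synthetic")
  attr(ds, "latent") <- stats::setNames(g, ids)
  attr(ds, "config") <- config
  ds
}

# save/restore the global RNG state so seeded generators do not disturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
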