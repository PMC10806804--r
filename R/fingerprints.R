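#' Schema of the 24-length flat fingerprint
#'
#' The flat fingerprint counts, over the whole molecular graph: total
#' hydrogens; total carbons; carbons per free-valence class C0--C3; total
#' free valence; carbon--carbon bonds by order (single, double, triple);
#' C--H bonds split by the carbon's free-valence class; and carbon--carbon
#' bonds split by the unordered pair of free-valence classes of their
#' endpoints. That is 2 + 4 + 1 + 3 + 4 + 10 = 24 features.
#'
#' @return Character vector of the 24 feature labels, in fingerprint order.
#' @export
flat_schema <- function() {
  pair_labels <- character(0)
  for (i in 0:3) for (j in i:3)
    pair_labels <- c(pair_labels, sprintf("C%d-C%d", i, j))
  c("H", "C", "C0", "C1", "C2", "C3", "FV",
    "C-C", "C=C", "C#C",
    "C0-H", "C1-H", "C2-H", "C3-H",
    pair_labels)
}

# schema identifier written into CSV headers so alternative layouts can
# coexist later
FLAT_SCHEMA_VERSION <- "flat24/v1"
MORGAN_SCHEMA_VERSION <- "morgan24/v1-binary"

#' 24-length flat fingerprint of a molecular graph
#'
#' Whole-graph counts of atoms, free valences and bond types as listed by
#' [flat_schema()]. All entries are non-negative integers; the vector is
#' invariant to the SMILES writing order because it only depends on the
#' labelled graph.
#'
#' @param graph A `molecular_graph` from [parse_smiles()].
#' @return A named numeric vector of length 24 with attributes `schema`
#'   (feature labels) and `kind` (`"flat24"`).
#' @examples
#' flat_fingerprint(parse_smiles("CCC"))
#' @export
flat_fingerprint <- function(graph) {
  validate_molecular_graph(graph)
  at <- graph$atoms
  bd <- graph$bonds
  sch <- flat_schema()
  v <- stats::setNames(numeric(length(sch)), sch)
  cls <- at$free_valence  # class Cx = free valence x
  v["H"] <- sum(at$hydrogen_count)
  v["C"] <- nrow(at)
  for (x in 0:3) v[sprintf("C%d", x)] <- sum(cls == x)
  v["FV"] <- sum(at$free_valence)
  if (nrow(bd) > 0L) {
    v["C-C"] <- sum(bd$order == 1L)
    v["C=C"] <- sum(bd$order == 2L)
    v["C#C"] <- sum(bd$order == 3L)
  }
  for (x in 0:3) v[sprintf("C%d-H", x)] <- sum(at$hydrogen_count[cls == x])
  for (b in seq_len(nrow(bd))) {
    i <- min(cls[bd$from[b]], cls[bd$to[b]])
    j <- max(cls[bd$from[b]], cls[bd$to[b]])
    lab <- sprintf("C%d-C%d", i, j)
    v[lab] <- v[lab] + 1
  }
  structure(v, schema = sch, kind = "flat24")
}

# stable 31-bit polynomial string hash (base 131 modulo the Mersenne prime
# 2^31 - 1); platform-independent because all intermediates stay below 2^53
stable_hash <- function(s) {
  p <- 2147483647
  h <- 7          # fixed seed
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% p
  h
}

#' Circular (Morgan) environment identifiers of a molecular graph
#'
#' For each atom, iteratively hashes its neighbourhood out to `radius`
#' bonds. The radius-0 invariant combines element, hydrogen count, free
#' valence, degree and sorted incident bond orders; each subsequent radius
#' combines the atom's previous identifier with the sorted (bond order,
#' neighbour identifier) pairs. An atom contributes a new identifier at
#' radius r only while its r-ball still grows, and duplicate identifiers
#' (equivalent environments) are counted once.
#'
#' @param graph A `molecular_graph`.
#' @param radius Maximum environment radius (bonds); default 2.
#' @return Numeric vector of distinct environment identifiers (31-bit
#'   integers stored as doubles).
#' @export
morgan_environments <- function(graph, radius = 2L) {
  validate_molecular_graph(graph)
  stopifnot(radius >= 0L)
  at <- graph$atoms
  n <- nrow(at)
  A <- adjacency_matrix(graph)
  neighbours <- lapply(seq_len(n), function(a) which(A[a, ] > 0L))

  ids <- vapply(seq_len(n), function(a) {
    inv <- paste("C", at$hydrogen_count[a], at$free_valence[a],
                 length(neighbours[[a]]),
                 paste(sort(A[a, neighbours[[a]]]), collapse = ","),
                 sep = "|")
    stable_hash(inv)
  }, numeric(1))

  balls <- lapply(seq_len(n), function(a) a)
  out <- unique(ids)
  if (radius > 0L) {
    for (r in seq_len(radius)) {
      grew <- rep(FALSE, n)
      new_balls <- balls
      for (a in seq_len(n)) {
        nb_ball <- sort(unique(c(balls[[a]], unlist(neighbours[balls[[a]]]))))
        grew[a] <- length(nb_ball) > length(balls[[a]])
        new_balls[[a]] <- nb_ball
      }
      env_strings <- vapply(seq_len(n), function(a) {
        parts <- c_sort(sprintf("%d:%.0f", A[a, neighbours[[a]]], ids[neighbours[[a]]]))
        paste(r, sprintf("%.0f", ids[a]), paste(parts, collapse = ";"), sep = "|")
      }, character(1))
      new_ids <- vapply(env_strings, stable_hash, numeric(1), USE.NAMES = FALSE)
      out <- c(out, new_ids[grew])
      ids <- new_ids
      balls <- new_balls
      if (!any(grew)) break
    }
  }
  unique(out)
}

#' 24-length Morgan fingerprint
#'
#' Folds the distinct circular-environment identifiers of
#' [morgan_environments()] modulo `nbits` into a binary presence vector.
#'
#' @param graph A `molecular_graph`.
#' @param radius Environment radius in bonds (default 2).
#' @param nbits Folded width (default 24).
#' @return A named numeric 0/1 vector of length `nbits` with attributes
#'   `schema` (bit labels) and `kind` (`"morgan24"`).
#' @examples
#' morgan_fingerprint(parse_smiles("C"))  # methane: a single set bit
#' @export
morgan_fingerprint <- function(graph, radius = 2L, nbits = 24L) {
  stopifnot(nbits >= 1L)
  ids <- morgan_environments(graph, radius)
  v <- numeric(nbits)
  v[(ids %% nbits) + 1] <- 1
  sch <- sprintf("bit%02d", seq_len(nbits) - 1L)
  structure(stats::setNames(v, sch), schema = sch, kind = "morgan24")
}

#' Fingerprint matrix for a set of SMILES
#'
#' @param smiles Character vector of SMILES strings.
#' @param kind `"flat24"` or `"morgan24"`.
#' @param radius,nbits Morgan parameters, ignored for `"flat24"`.
#' @return Numeric matrix, one row per input, columns labelled by the
#'   fingerprint schema; rownames taken from `names(smiles)` if present.
#' @export
fingerprint_matrix <- function(smiles, kind = c("flat24", "morgan24"),
                               radius = 2L, nbits = 24L) {
  kind <- match.arg(kind)
  rows <- lapply(smiles, function(s) {
    g <- parse_smiles(s)
    if (kind == "flat24") flat_fingerprint(g)
    else morgan_fingerprint(g, radius = radius, nbits = nbits)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(smiles)
  m
}

#' Load precomputed embedding fingerprints
#'
#' Reads a table of externally computed per-species embedding vectors (for
#' example from a pretrained SMILES language model), one row per species:
#' a `species_id` column followed by numeric columns of equal width.
#'
#' @param path Path to a CSV file.
#' @return Named list of numeric embedding vectors keyed by species id,
#'   with attribute `d` (embedding width); an empty list for an empty file.
#' @export
load_embeddings <- function(path) {
  if (!file.exists(path)) stop(sprintf("embedding file not found: %s", path), call. = FALSE)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
                 error = function(e) stop(sprintf("embedding format error in %s: %s",
                                                  path, conditionMessage(e)), call. = FALSE))
  if (nrow(df) == 0L) return(structure(list(), d = max(0L, ncol(df) - 1L)))
  if (!"species_id" %in% names(df))
    stop(sprintf("embedding format error in %s: missing species_id column", path), call. = FALSE)
  ids <- as.character(df$species_id)
  if (anyDuplicated(ids))
    stop(sprintf("embedding format error in %s: duplicated species id(s) %s",
                 path, paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  num <- df[, setdiff(names(df), "species_id"), drop = FALSE]
  if (ncol(num) == 0L)
    stop(sprintf("embedding format error in %s: no numeric columns", path), call. = FALSE)
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad))
    stop(sprintf("embedding format error in %s: non-numeric column(s) %s",
                 path, paste(names(num)[bad], collapse = ", ")), call. = FALSE)
  if (anyNA(num))
    stop(sprintf("embedding format error in %s: missing values", path), call. = FALSE)
  d <- ncol(num)
  out <- lapply(seq_len(nrow(num)), function(i) {
    v <- as.numeric(num[i, ])
    structure(v, schema = names(num), kind = "embedding")
  })
  names(out) <- ids
  structure(out, d = d)
}
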