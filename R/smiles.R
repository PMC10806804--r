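#' Parse a SMILES string for a C/H surface intermediate
#'
#' Parses the restricted SMILES dialect used for hydrocarbon surface
#' intermediates: carbon atoms written bare (`C`, implicit hydrogens fill the
#' valence to 4) or in brackets with an explicit hydrogen count (`[CH3]`,
#' `[CH2]`, `[CH]`, `[C]` in a bonded context), bond symbols `-`, `=`, `#`,
#' parenthesised branches, and ring-closure digits. A bracket atom's free
#' valence -- the number of dangling bonds it presents to the surface -- is
#' whatever of the carbon valence of 4 is left after explicit hydrogens and
#' bonds. Free valences from 0 to 3 are supported (classes C0--C3); a carbon
#' whose computed free valence falls outside that range is rejected.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `molecular_graph`: a list with components
#'   `atoms` (data frame with columns `element`, `hydrogen_count`,
#'   `free_valence`) and `bonds` (data frame with columns `from`, `to`,
#'   `order`).
#' @examples
#' parse_smiles("CCC")      # propane
#' parse_smiles("[CH2]C")   # ethylidene-type radical, one free valence
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles))
    stop("`smiles` must be a single character string", call. = FALSE)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  n_char <- length(chars)
  if (n_char == 0L)
    stop("SMILES parse error at position 1: empty string", call. = FALSE)

  perr <- function(pos, what)
    stop(sprintf("SMILES parse error at position %d in \"%s\": %s",
                 pos, smiles, what), call. = FALSE)

  atoms <- list()       # per atom: list(h = explicit H or NA, bracket = TRUE/FALSE)
  bonds <- list()       # list(from, to, order)
  prev <- NA_integer_   # atom awaiting the next bond
  stack <- integer(0)   # branch stack
  pending <- NA_integer_ # bond order set by an explicit bond symbol
  ring <- list()        # digit -> list(atom, order)

  add_atom <- function(h, bracket) {
    atoms[[length(atoms) + 1L]] <<- list(h = h, bracket = bracket)
    idx <- length(atoms)
    if (!is.na(prev)) {
      ord <- if (is.na(pending)) 1L else pending
      bonds[[length(bonds) + 1L]] <<- list(from = prev, to = idx, order = ord)
    }
    pending <<- NA_integer_
    prev <<- idx
  }

  i <- 1L
  while (i <= n_char) {
    ch <- chars[i]
    if (ch == "C") {
      add_atom(NA_integer_, bracket = FALSE)
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      if (j > n_char || chars[j] != "C") {
        if (j <= n_char && chars[j] %in% c("c", "n", "o", "s"))
          perr(j, "aromatic atoms are not supported in this dialect")
        perr(j, "expected a carbon atom after '['")
      }
      j <- j + 1L
      h <- 0L
      if (j <= n_char && chars[j] == "H") {
        j <- j + 1L
        h <- 1L
        if (j <= n_char && grepl("^[0-9]$", chars[j])) {
          h <- as.integer(chars[j])
          j <- j + 1L
        }
      }
      if (j > n_char || chars[j] != "]")
        perr(j, "expected ']' closing the bracket atom")
      add_atom(h, bracket = TRUE)
      i <- j + 1L
    } else if (ch == "-" || ch == "=" || ch == "#") {
      if (!is.na(pending)) perr(i, "two consecutive bond symbols")
      pending <- c("-" = 1L, "=" = 2L, "#" = 3L)[[ch]]
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) perr(i, "branch before any atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) perr(i, "unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[1-9]$", ch)) {
      if (is.na(prev)) perr(i, "ring closure before any atom")
      if (is.null(ring[[ch]])) {
        ring[[ch]] <- list(atom = prev,
                           order = if (is.na(pending)) NA_integer_ else pending)
      } else {
        open <- ring[[ch]]
        ord <- if (!is.na(pending)) pending
               else if (!is.na(open$order)) open$order else 1L
        if (open$atom == prev) perr(i, "ring closure bonds an atom to itself")
        bonds[[length(bonds) + 1L]] <- list(from = open$atom, to = prev,
                                            order = ord)
        ring[[ch]] <- NULL
      }
      pending <- NA_integer_
      i <- i + 1L
    } else if (ch == ".") {
      perr(i, "disconnected components ('.') are not supported")
    } else if (ch == "c") {
      perr(i, "aromatic atoms are not supported in this dialect")
    } else {
      perr(i, sprintf("unexpected character '%s'", ch))
    }
  }
  if (length(stack) > 0L) perr(n_char, "unmatched '('")
  if (length(ring) > 0L) perr(n_char, "unclosed ring bond")
  if (!is.na(pending)) perr(n_char, "dangling bond symbol")

  n <- length(atoms)
  bond_df <- if (length(bonds) == 0L) {
    data.frame(from = integer(0), to = integer(0), order = integer(0))
  } else {
    data.frame(from = vapply(bonds, `[[`, 1L, "from"),
               to = vapply(bonds, `[[`, 1L, "to"),
               order = vapply(bonds, `[[`, 1L, "order"))
  }
  bond_sum <- rep(0L, n)
  for (b in seq_len(nrow(bond_df))) {
    bond_sum[bond_df$from[b]] <- bond_sum[bond_df$from[b]] + bond_df$order[b]
    bond_sum[bond_df$to[b]] <- bond_sum[bond_df$to[b]] + bond_df$order[b]
  }

  hyd <- integer(n)
  fv <- integer(n)
  for (a in seq_len(n)) {
    if (atoms[[a]]$bracket) {
      hyd[a] <- atoms[[a]]$h
      fv[a] <- 4L - hyd[a] - bond_sum[a]
    } else {
      # implicit-H rule: hydrogens fill carbon valence to 4, free valence 0
      hyd[a] <- 4L - bond_sum[a]
      fv[a] <- 0L
    }
    if (hyd[a] < 0L)
      stop(sprintf("valence error in \"%s\": atom %d carries bonds beyond carbon valence 4",
                   smiles, a), call. = FALSE)
    if (fv[a] < 0L || fv[a] > 3L)
      stop(sprintf("valence error in \"%s\": atom %d has free valence %d, outside the supported C0-C3 classes",
                   smiles, a, fv[a]), call. = FALSE)
  }

  graph <- structure(
    list(atoms = data.frame(element = rep("C", n),
                            hydrogen_count = hyd,
                            free_valence = fv),
         bonds = bond_df),
    class = "molecular_graph")
  validate_molecular_graph(graph)
  graph
}

#' Validate a molecular graph
#'
#' Checks the structural invariants of a [parse_smiles()] result: the carbon
#' valence identity (hydrogens + free valence + bond orders = 4 on every
#' atom), valid bond endpoints, bond orders in 1--3, free valences in 0--3
#' and connectivity.
#'
#' @param graph A `molecular_graph`.
#' @return `graph`, invisibly; errors if an invariant is violated.
#' @export
validate_molecular_graph <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  at <- graph$atoms
  bd <- graph$bonds
  n <- nrow(at)
  if (n < 1L) stop("molecular graph has no atoms", call. = FALSE)
  if (nrow(bd) > 0L) {
    if (any(bd$from < 1L | bd$from > n | bd$to < 1L | bd$to > n))
      stop("bond references an atom index out of range", call. = FALSE)
    if (any(bd$from == bd$to)) stop("self-bond in molecular graph", call. = FALSE)
    if (any(bd$order < 1L | bd$order > 3L))
      stop("bond order outside 1-3", call. = FALSE)
  }
  bs <- bond_order_sums(graph)
  bad <- which(at$hydrogen_count + at$free_valence + bs != 4L)
  if (length(bad) > 0L)
    stop(sprintf("carbon valence identity violated at atom(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (any(at$free_valence < 0L | at$free_valence > 3L))
    stop("free valence outside the supported C0-C3 classes", call. = FALSE)
  # connectivity by breadth-first search
  if (n > 1L) {
    seen <- rep(FALSE, n)
    seen[1L] <- TRUE
    frontier <- 1L
    while (length(frontier) > 0L) {
      nxt <- integer(0)
      for (b in seq_len(nrow(bd))) {
        if (seen[bd$from[b]] && !seen[bd$to[b]]) { seen[bd$to[b]] <- TRUE; nxt <- c(nxt, bd$to[b]) }
        if (seen[bd$to[b]] && !seen[bd$from[b]]) { seen[bd$from[b]] <- TRUE; nxt <- c(nxt, bd$from[b]) }
      }
      frontier <- nxt
    }
    if (!all(seen)) stop("molecular graph is not connected", call. = FALSE)
  }
  invisible(graph)
}

# sum of incident bond orders per atom
bond_order_sums <- function(graph) {
  n <- nrow(graph$atoms)
  bs <- rep(0L, n)
  bd <- graph$bonds
  for (b in seq_len(nrow(bd))) {
    bs[bd$from[b]] <- bs[bd$from[b]] + bd$order[b]
    bs[bd$to[b]] <- bs[bd$to[b]] + bd$order[b]
  }
  bs
}

# dense symmetric bond-order adjacency matrix
adjacency_matrix <- function(graph) {
  n <- nrow(graph$atoms)
  A <- matrix(0L, n, n)
  bd <- graph$bonds
  for (b in seq_len(nrow(bd))) {
    A[bd$from[b], bd$to[b]] <- bd$order[b]
    A[bd$to[b], bd$from[b]] <- bd$order[b]
  }
  A
}

#' Test two molecular graphs for isomorphism
#'
#' Exhaustive permutation search matching atom labels (hydrogen count, free
#' valence) and the bond-order adjacency structure. Intended for the small
#' graphs of surface intermediates (a handful of heavy atoms).
#'
#' @param g1,g2 `molecular_graph` objects.
#' @return `TRUE` if the labelled graphs are isomorphic.
#' @export
graph_isomorphic <- function(g1, g2) {
  n <- nrow(g1$atoms)
  if (n != nrow(g2$atoms)) return(FALSE)
  lab1 <- paste(g1$atoms$hydrogen_count, g1$atoms$free_valence)
  lab2 <- paste(g2$atoms$hydrogen_count, g2$atoms$free_valence)
  if (!identical(c_sort(lab1), c_sort(lab2))) return(FALSE)
  if (n > 8L) stop("graph_isomorphic supports at most 8 atoms", call. = FALSE)
  A1 <- adjacency_matrix(g1)
  A2 <- adjacency_matrix(g2)
  for (p in all_permutations(n)) {
    if (all(lab1 == lab2[p]) && all(A1 == A2[p, p, drop = FALSE])) return(TRUE)
  }
  FALSE
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_permutations(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

# serialize with a fixed atom visiting priority; spanning tree by DFS,
# remaining edges become ring closures
write_smiles_ordered <- function(graph, perm) {
  n <- nrow(graph$atoms)
  A <- adjacency_matrix(graph)
  at <- graph$atoms
  pr <- integer(n); pr[perm] <- seq_len(n)  # priority rank per atom

  atom_token <- function(a) {
    # the valence identity makes the implicit-H rule exact whenever fv = 0
    if (at$free_valence[a] == 0L) return("C")
    h <- at$hydrogen_count[a]
    if (h == 0L) "[C]" else if (h == 1L) "[CH]" else sprintf("[CH%d]", h)
  }
  bond_token <- function(o) c("", "=", "#")[o]

  visited <- rep(FALSE, n)
  ring_id <- 0L
  ring_marks <- vector("list", n)  # per atom: list of (digit, order)
  tree_children <- vector("list", n)
  parent <- rep(NA_integer_, n)

  root <- perm[1L]
  order_visit <- integer(0)
  visit <- function(a) {
    visited[a] <<- TRUE
    order_visit <<- c(order_visit, a)
    nb <- which(A[a, ] > 0L)
    for (b in nb[order(pr[nb])]) {
      if (!visited[b]) {
        parent[b] <<- a
        tree_children[[a]] <<- c(tree_children[[a]], b)
        visit(b)
      }
    }
  }
  visit(root)

  # back edges -> ring closure digits
  done <- matrix(FALSE, n, n)
  for (a in seq_len(n)) {
    if (!is.na(parent[a])) { done[a, parent[a]] <- TRUE; done[parent[a], a] <- TRUE }
  }
  for (a in order_visit) {
    for (b in which(A[a, ] > 0L)) {
      if (!done[a, b]) {
        ring_id <- ring_id + 1L
        if (ring_id > 9L) stop("more than 9 ring closures unsupported", call. = FALSE)
        ring_marks[[a]] <- c(ring_marks[[a]], list(list(d = ring_id, o = A[a, b])))
        ring_marks[[b]] <- c(ring_marks[[b]], list(list(d = ring_id, o = 1L)))
        done[a, b] <- TRUE; done[b, a] <- TRUE
      }
    }
  }

  emit <- function(a) {
    s <- atom_token(a)
    for (m in ring_marks[[a]]) {
      s <- paste0(s, if (m$o > 1L) bond_token(m$o) else "", m$d)
    }
    ch <- tree_children[[a]]
    if (length(ch) > 0L) {
      for (i in seq_along(ch)) {
        sub <- paste0(bond_token(A[a, ch[i]]), emit(ch[i]))
        s <- paste0(s, if (i < length(ch)) paste0("(", sub, ")") else sub)
      }
    }
    s
  }
  emit(root)
}

#' Canonical SMILES for a molecular graph
#'
#' Returns the lexicographically smallest serialisation over all atom
#' orderings, so isomorphic graphs map to the same string. Exhaustive over
#' atom permutations; intended for intermediates with few heavy atoms.
#'
#' @param graph A `molecular_graph`.
#' @return A single SMILES string in the supported dialect.
#' @export
canonical_smiles <- function(graph) {
  n <- nrow(graph$atoms)
  if (n > 7L) stop("canonical_smiles supports at most 7 atoms", call. = FALSE)
  # prefer unbranched serialisations (fewest parentheses), then the smallest
  # string under C collation (locale-independent)
  cand <- vapply(all_permutations(n),
                 function(p) write_smiles_ordered(graph, p), character(1))
  np <- lengths(regmatches(cand, gregexpr("(", cand, fixed = TRUE)))
  cand[order(np, cand, method = "radix")[1L]]
}
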