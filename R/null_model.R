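# Degree-preserving randomisation (Curveball) and null-ensemble motif
# statistics. The web is viewed as rows = consumers holding their resource
# sets; one trade exchanges a random-sized random subset of two rows'
# exclusive elements, which preserves every node's in- and out-degree.

#' One Curveball trade
#'
#' Reference implementation operating on the adjacency-set view: a named
#' list mapping each consumer to the (character) vector of its resources.
#' Two distinct rows are chosen at random and a random subset of their
#' exclusive elements is exchanged. Elements equal to the other row's owner
#' are withheld from the trade so no self-link can arise.
#'
#' @param rows named list of resource-id vectors, one per consumer.
#' @return the modified list (row and column margins unchanged).
#' @export
curveball_trade <- function(rows) {
  if (length(rows) < 2) return(rows)
  ab <- sample(length(rows), 2)
  a <- ab[1]; b <- ab[2]
  owner_a <- names(rows)[a]; owner_b <- names(rows)[b]
  ra <- rows[[a]]; rb <- rows[[b]]
  shared <- intersect(ra, rb)
  ex_a <- setdiff(ra, rb); ex_b <- setdiff(rb, ra)
  fixed_a <- ex_a[ex_a == owner_b]; ex_a <- ex_a[ex_a != owner_b]
  fixed_b <- ex_b[ex_b == owner_a]; ex_b <- ex_b[ex_b != owner_a]
  if (!length(ex_a) || !length(ex_b)) return(rows)
  pool <- sample(c(ex_a, ex_b))
  rows[[a]] <- c(shared, fixed_a, pool[seq_along(ex_a)])
  rows[[b]] <- c(shared, fixed_b, pool[-seq_along(ex_a)])
  rows
}

.web_rows <- function(bweb) {
  split(bweb$edges$from, factor(bweb$edges$to,
                                levels = unique(bweb$edges$to)))
}

#' Degree-preserving rewiring of a binary web
#'
#' Applies `n_trades` Curveball trades. Node set, link count, and the in-
#' and out-degree of every node are preserved exactly, so structural role
#' constraints (e.g. plants never acquire incoming feeding links) are
#' maintained automatically.
#'
#' @param bweb a `binary_web`.
#' @param n_trades number of trades; defaults to 5 x number of consumer rows.
#' @param seed optional integer seed.
#' @return a rewired `binary_web`.
#' @export
rewire <- function(bweb, n_trades = NULL, seed = NULL) {
  stopifnot(inherits(bweb, "binary_web"))
  if (!is.null(seed)) set.seed(seed)
  n_rows <- length(unique(bweb$edges$to))
  if (is.null(n_trades)) n_trades <- 5L * n_rows
  if (n_trades == 0 || nrow(bweb$edges) == 0) return(bweb)
  ei <- .edges_to_int(bweb$edges, bweb$nodes)
  rw <- curveball_rewire_cpp(ei$from, ei$to, length(bweb$nodes), n_trades)
  out <- bweb
  out$edges <- data.frame(from = bweb$nodes[rw$from + 1L],
                          to = bweb$nodes[rw$to + 1L],
                          stringsAsFactors = FALSE)
  out
}

#' Null-ensemble motif statistics
#'
#' Generates `R` independent rewirings (each a fresh trade sequence started
#' from the original web) and returns the per-class mean and standard
#' deviation of their motif counts.
#'
#' @param bweb a `binary_web`.
#' @param R ensemble size (default 250).
#' @param trades_factor trades per sample as a multiple of the number of
#'   consumer rows (default 5).
#' @param seed optional integer seed.
#' @return list with `mean`, `sd` (13-vectors), `R`, and the raw `counts`
#'   matrix (R x 13).
#' @export
null_ensemble <- function(bweb, R = 250, trades_factor = 5, seed = NULL) {
  stopifnot(inherits(bweb, "binary_web"), R >= 2)
  if (!is.null(seed)) set.seed(seed)
  n <- length(bweb$nodes)
  n_rows <- length(unique(bweb$edges$to))
  if (nrow(bweb$edges) == 0 || n < 3) {
    zero <- setNames(numeric(13), names(.motif_map))
    return(list(mean = zero, sd = zero, R = R,
                counts = matrix(0, R, 13,
                                dimnames = list(NULL, names(.motif_map)))))
  }
  ei <- .edges_to_int(bweb$edges, bweb$nodes)
  c16 <- ensemble_census_cpp(ei$from, ei$to, n, R, trades_factor * n_rows)
  counts <- c16[, match(.motif_map, .triad16), drop = FALSE]
  colnames(counts) <- names(.motif_map)
  list(mean = colMeans(counts), sd = apply(counts, 2, sd), R = R,
       counts = counts)
}
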