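# Triad (three-species motif) classification and census. The 13 connected
# directed triads are labelled s1-s5 (single links only) and d1-d8 (at least
# one double link); the census is induced, so every unordered node triple is
# assigned to exactly one class (the densest arrangement it forms), or to
# "disconnected".

# Standard 16-type triad nomenclature in census order.
.triad16 <- c("003", "012", "102", "021D", "021U", "021C", "111D", "111U",
              "030T", "030C", "201", "120D", "120U", "120C", "210", "300")

# 6-bit induced-subgraph code -> index into .triad16 (same table as the
# compiled census uses). Bits: 1 u->v, 2 v->u, 4 u->w, 8 w->u, 16 v->w,
# 32 w->v.
.tri_type <- c(0,1,1,2,1,3,5,7,1,5,4,6,2,7,6,10,
               1,5,3,7,4,8,8,12,5,9,8,13,6,13,11,14,
               1,4,5,6,5,8,9,13,3,8,8,11,7,12,13,14,
               2,6,7,10,6,11,13,14,7,13,12,14,10,14,14,15) + 1L

# Motif code -> 16-type name. With edges directed resource -> consumer:
# s1 tri-trophic chain, s2 omnivory, s3 directed loop, s4 apparent
# competition (two resources -> one consumer), s5 exploitative competition
# (one resource -> two consumers); d1-d8 cover the eight classes with at
# least one mutual (double) link.
.motif_map <- c(s1 = "021C", s2 = "030T", s3 = "030C", s4 = "021U",
                s5 = "021D", d1 = "111D", d2 = "111U", d3 = "201",
                d4 = "120D", d5 = "120U", d6 = "120C", d7 = "210",
                d8 = "300")

#' The 13 connected triad classes
#'
#' Mapping between the motif codes used throughout the package (s1-s5,
#' d1-d8) and the standard 16-type triad census nomenclature, with short
#' ecological descriptions for the named motifs.
#'
#' @return data frame with columns `code`, `triad_type`, `description`.
#' @export
motif_classes <- function() {
  data.frame(
    code = names(.motif_map),
    triad_type = unname(.motif_map),
    description = c(
      "tri-trophic chain (A->B->C)",
      "omnivory (top consumer feeds on both lower species)",
      "directed loop (feed-forward cycle)",
      "apparent competition (two resources share a consumer)",
      "exploitative competition (one resource shared by two consumers)",
      rep("double-link triad", 8)),
    stringsAsFactors = FALSE)
}

.triad_code <- function(has, u, v, w) {
  # has(a, b): does edge a->b exist
  (if (has(u, v)) 1L else 0L) + (if (has(v, u)) 2L else 0L) +
  (if (has(u, w)) 4L else 0L) + (if (has(w, u)) 8L else 0L) +
  (if (has(v, w)) 16L else 0L) + (if (has(w, v)) 32L else 0L)
}

#' Classify the induced triad on three labelled nodes
#'
#' @param edges two-column data frame or matrix (`from`, `to`) of directed
#'   feeding links among exactly three nodes; may be empty.
#' @param nodes optional character vector naming the three nodes (required
#'   when some are isolated).
#' @return the motif code (`"s1"`..`"d8"`) or `"disconnected"` when the
#'   underlying undirected graph on the three nodes is not connected.
#' @export
classify_triad <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    names(edges)[1:2] <- c("from", "to")
    if (any(edges$from == edges$to))
      stop("self-loops are not allowed", call. = FALSE)
  }
  ids <- unique(c(nodes, if (nrow(edges)) c(edges$from, edges$to)))
  if (length(ids) != 3)
    stop("exactly three nodes are required, got ", length(ids), call. = FALSE)
  key <- if (nrow(edges)) paste(edges$from, edges$to, sep = "\r") else character()
  has <- function(a, b) paste(a, b, sep = "\r") %in% key
  type <- .triad16[.tri_type[.triad_code(has, ids[1], ids[2], ids[3]) + 1L]]
  if (type %in% c("003", "012", "102")) return("disconnected")
  names(.motif_map)[match(type, .motif_map)]
}

.counts_from_census16 <- function(cens16) {
  setNames(cens16[match(.motif_map, .triad16)], names(.motif_map))
}

.edges_to_int <- function(edges, nodes) {
  list(from = match(edges$from, nodes) - 1L,
       to = match(edges$to, nodes) - 1L)
}

#' Motif census of a binary web
#'
#' Induced triad census over all unordered node triples: each connected
#' triple contributes to exactly one of the 13 classes, so e.g. an omnivory
#' (s2) triple is not additionally counted as the chain and competition
#' motifs embedded in it.
#'
#' @param bweb a `binary_web`.
#' @return named 13-vector of class counts (class `motif_counts`), with the
#'   number of nodes and the disconnected-triple count as attributes.
#' @export
census <- function(bweb) {
  stopifnot(inherits(bweb, "binary_web"))
  n <- length(bweb$nodes)
  if (n < 3) {
    out <- setNames(numeric(13), names(.motif_map))
  } else {
    ei <- .edges_to_int(bweb$edges, bweb$nodes)
    c16 <- triad_census16_cpp(ei$from, ei$to, n)
    out <- .counts_from_census16(c16)
    attr(out, "disconnected") <- sum(c16[1:3])
  }
  attr(out, "n_nodes") <- n
  class(out) <- c("motif_counts", class(out))
  out
}

#' Mean motif counts over sampling iterations
#'
#' Samples the probability matrix repeatedly, counting motifs on the full
#' web and on the consumer sub-web (free-floating motifs) of the same
#' sampled iteration, and averages per class.
#'
#' @param pweb a `prob_web`.
#' @param iterations number of sampled webs (default 50).
#' @param seed integer seed.
#' @return list with `full` and `free_floating` mean 13-vectors, the
#'   per-class `grounded_fraction` (share of motifs containing a basal node,
#'   defined where the full-web mean is positive), and the per-iteration
#'   count matrices.
#' @export
census_profile <- function(pweb, iterations = 50, seed = 1) {
  stopifnot(inherits(pweb, "prob_web"), iterations >= 1)
  full <- sub <- matrix(0, iterations, 13,
                        dimnames = list(NULL, names(.motif_map)))
  for (it in seq_len(iterations)) {
    bw <- sample_binary_web(pweb, seed = derive_seed(seed, pweb$plot_id,
                                                     pweb$time_period, it),
                            iteration = it)
    full[it, ] <- as.numeric(census(bw))
    sub[it, ] <- as.numeric(census(consumer_subweb(bw)))
  }
  mf <- colMeans(full)
  ms <- colMeans(sub)
  gf <- ifelse(mf > 0, (mf - ms) / mf, NA_real_)
  list(full = mf, free_floating = ms, grounded_fraction = gf,
       per_iteration = list(full = full, free_floating = sub))
}
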