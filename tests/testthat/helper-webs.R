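# Helpers for building small webs and communities in code.

# Binary web over named consumer nodes from an edge data frame.
make_web <- function(edges, nodes = NULL, roles = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges)[1:2] <- c("from", "to")
  ids <- unique(c(nodes, edges$from, edges$to))
  if (is.null(roles)) roles <- setNames(rep("consumer", length(ids)), ids)
  structure(list(plot_id = "p", time_period = "t", iteration = NA_integer_,
                 nodes = ids, roles = roles[ids], edges = edges),
            class = "binary_web")
}

# Random directed graph (no self-loops) as a binary web.
random_web <- function(n, p) {
  A <- matrix(runif(n * n) < p, n, n)
  diag(A) <- FALSE
  ids <- sprintf("v%03d", seq_len(n))
  idx <- which(A, arr.ind = TRUE)
  make_web(data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      stringsAsFactors = FALSE), nodes = ids)
}

# Probability web built directly from a named probability matrix.
make_pweb <- function(A, roles = NULL) {
  ids <- rownames(A)
  if (is.null(roles)) roles <- setNames(rep("consumer", length(ids)), ids)
  structure(list(plot_id = "p", time_period = "t", nodes = ids,
                 roles = roles[ids], A = A, sown_richness = 1L,
                 block_id = "B1"),
            class = "prob_web")
}

# A tiny hand-built community: 2 plants, 2 static resources, 4 consumers.
tiny_community <- function() {
  nodes <- data.frame(
    id = c("p1", "p2", "detritus", "moss", "herb1", "det1", "omn1", "pred1"),
    role = c("plant", "plant", "static_resource", "static_resource",
             "consumer", "consumer", "consumer", "consumer"),
    guild = c("none", "none", "none", "none",
              "herbivore", "detritivore", "omnivore", "predator"),
    stratum = c("none", "none", "none", "none", "herb", "ground", "both",
                "both"),
    body_length_mm = c(NA, NA, NA, NA, 4, 5, 6, 8),
    stringsAsFactors = FALSE)
  metaweb <- data.frame(
    resource_id = c("p1", "p2", "detritus", "p1", "herb1", "det1", "herb1"),
    consumer_id = c("herb1", "herb1", "det1", "omn1", "omn1", "pred1",
                    "pred1"),
    link_type = c(1L, 2L, 3L, 2L, 4L, 4L, 5L),
    stringsAsFactors = FALSE)
  design <- data.frame(plot_id = c("plotA", "plotB"),
                       block_id = c("B1", "B1"),
                       sown_richness = c(1L, 2L), stringsAsFactors = FALSE)
  samples <- rbind(
    data.frame(plot_id = "plotA", time_period = "T1", node_id = "p1",
               value = 0.8, value_kind = "cover", stringsAsFactors = FALSE),
    data.frame(plot_id = "plotA", time_period = "T1",
               node_id = c("herb1", "det1", "omn1", "pred1"),
               value = c(10, 5, 2, 3), value_kind = "count",
               stringsAsFactors = FALSE),
    data.frame(plot_id = "plotB", time_period = "T1",
               node_id = c("p1", "p2"), value = c(0.5, 0.3),
               value_kind = "cover", stringsAsFactors = FALSE),
    data.frame(plot_id = "plotB", time_period = "T1",
               node_id = c("herb1", "pred1"), value = c(8, 2),
               value_kind = "count", stringsAsFactors = FALSE))
  community(nodes, metaweb, design, samples)
}

# Subset a generated community to the first k plots of each richness level.
subset_community <- function(comm, k) {
  keep <- unlist(lapply(split(comm$design$plot_id, comm$design$sown_richness),
                        function(x) head(x, k)))
  community(comm$nodes, comm$metaweb,
            comm$design[comm$design$plot_id %in% keep, ],
            comm$samples[comm$samples$plot_id %in% keep, ])
}

# Simulate a response on the experimental design with known fixed slope
# (per doubling of sown richness) and random intercepts for period, block
# and plot.
simulate_response <- function(design, slope, sd_period = 0.05,
                              sd_block = 0.05, sd_plot = 0.08,
                              sd_resid = 0.1, periods = 4) {
  d <- design[rep(seq_len(nrow(design)), periods), ]
  d$time_period <- rep(sprintf("T%d", seq_len(periods)),
                       each = nrow(design))
  u_p <- rnorm(periods, 0, sd_period)
  u_b <- rnorm(length(unique(d$block_id)), 0, sd_block)
  u_pl <- rnorm(length(unique(d$plot_id)), 0, sd_plot)
  d$y <- slope * log2(d$sown_richness) +
    u_p[match(d$time_period, sprintf("T%d", seq_len(periods)))] +
    u_b[match(d$block_id, unique(d$block_id))] +
    u_pl[match(d$plot_id, unique(d$plot_id))] +
    rnorm(nrow(d), 0, sd_resid)
  d
}

# In/out degree vectors of a binary web over a fixed node universe.
web_degrees <- function(bweb, ids) {
  list(out = table(factor(bweb$edges$from, levels = ids)),
       inn = table(factor(bweb$edges$to, levels = ids)))
}
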