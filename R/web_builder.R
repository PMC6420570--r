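# Probabilistic web construction: abundance-dependent encounter probabilities
# layered over the metaweb, binary sampling, pruning and consumer sub-webs.

#' Encounter-probability scalars
#'
#' `alpha` scales plant-consumer encounter probabilities (metaweb link types
#' 2-3 with a plant resource); `beta` scales predator-prey encounters (link
#' types 4-5).
#'
#' @param alpha positive scalar for plant-consumer encounters.
#' @param beta positive scalar for predator-prey encounters.
#' @export
scalar_config <- function(alpha, beta) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 ||
      !is.numeric(beta) || length(beta) != 1 || beta <= 0)
    stop("alpha and beta must be single positive numbers", call. = FALSE)
  structure(list(alpha = alpha, beta = beta), class = "scalar_config")
}

#' Interaction probability for one metaweb link
#'
#' Combines metaweb support with an abundance-dependent encounter
#' probability. With a link present, the probability is 1 for link type 1 and
#' for types 2-3 with a consumer or static resource as the resource;
#' `min(1, alpha * n_i * n_j)` for types 2-3 with a plant resource; and
#' `min(1, beta * n_i * n_j)` for types 4-5. Products exceeding 1 are clipped
#' because the result is used as a Bernoulli probability. All arguments are
#' vectorised.
#'
#' @param link_type integer vector in 1..5.
#' @param resource_role `"plant"`, `"static_resource"` or `"consumer"`.
#' @param n_resource,n_consumer relative cover/abundance in `[0,1]`.
#' @param scalars a [scalar_config()].
#' @return numeric vector of probabilities in `[0,1]`.
#' @export
interaction_probability <- function(link_type, resource_role, n_resource,
                                    n_consumer, scalars) {
  stopifnot(inherits(scalars, "scalar_config"))
  link_type <- as.integer(link_type)
  if (any(!link_type %in% 1:5))
    stop("unknown link type: ", paste(setdiff(link_type, 1:5), collapse = ", "),
         call. = FALSE)
  if (any(!resource_role %in% .roles))
    stop("unknown resource role", call. = FALSE)
  if (any(n_resource < 0 | n_resource > 1 | n_consumer < 0 | n_consumer > 1,
          na.rm = TRUE))
    stop("relative abundances must lie in [0,1]", call. = FALSE)

  k <- pmax(length(link_type), length(resource_role), length(n_resource),
            length(n_consumer))
  link_type <- rep_len(link_type, k)
  resource_role <- rep_len(resource_role, k)
  n_resource <- rep_len(as.numeric(n_resource), k)
  n_consumer <- rep_len(as.numeric(n_consumer), k)

  p <- numeric(k)
  t1 <- link_type == 1
  t23 <- link_type %in% 2:3
  t45 <- link_type %in% 4:5
  p[t1] <- 1
  cert <- t23 & resource_role != "plant"
  p[cert] <- 1
  dens <- t23 & resource_role == "plant"
  p[dens] <- pmin(1, scalars$alpha * n_resource[dens] * n_consumer[dens])
  p[t45] <- pmin(1, scalars$beta * n_resource[t45] * n_consumer[t45])
  p
}

#' Relative abundances for one plot-period
#'
#' Plants: relative cover renormalised over the plants present. Consumers:
#' counts normalised separately within the ground and herb strata; a species
#' using both strata contributes to both totals and takes the mean of its two
#' within-stratum shares.
#'
#' @param sample a [plot_sample()] list.
#' @param nodes the community node table.
#' @return named numeric vector over present plants and consumers.
#' @export
relative_abundances <- function(sample, nodes) {
  out <- numeric(0)
  pc <- sample$plant_cover
  if (length(pc)) out <- c(out, pc / sum(pc))
  ca <- sample$consumer_abundance
  if (length(ca)) {
    strat <- setNames(nodes$stratum, nodes$id)[names(ca)]
    g_tot <- sum(ca[strat %in% c("ground", "both")])
    h_tot <- sum(ca[strat %in% c("herb", "both")])
    n <- numeric(length(ca))
    for (i in seq_along(ca)) {
      n[i] <- switch(strat[i],
        ground = ca[i] / g_tot,
        herb   = ca[i] / h_tot,
        both   = mean(c(if (g_tot > 0) ca[i] / g_tot,
                        if (h_tot > 0) ca[i] / h_tot)))
    }
    n[!is.finite(n)] <- 0
    out <- c(out, setNames(n, names(ca)))
  }
  out
}

#' Build the probability matrix for one plot-period
#'
#' Restricts the metaweb to the species co-occurring on the plot in that
#' period (plants with nonzero cover, consumers with nonzero counts, plus all
#' static resource nodes) and fills the interaction probability for every
#' supported link.
#'
#' @param comm a `motifweb_community`.
#' @param plot_id,time_period which plot-period to build.
#' @param scalars a [scalar_config()].
#' @return a `prob_web`: node ids, their roles, and the probability matrix
#'   `A` indexed (resource, consumer).
#' @export
build_probabilistic_web <- function(comm, plot_id, time_period, scalars) {
  smp <- plot_sample(comm, plot_id, time_period)
  if (!length(smp$plant_cover) && !length(smp$consumer_abundance))
    stop(sprintf("degenerate plot-period %s/%s: no plants and no consumers",
                 plot_id, time_period), call. = FALSE)
  ids <- c(names(smp$plant_cover), smp$static_resources,
           names(smp$consumer_abundance))
  roles <- setNames(comm$nodes$role, comm$nodes$id)[ids]
  n_rel <- relative_abundances(smp, comm$nodes)

  mw <- comm$metaweb
  keep <- mw$resource_id %in% ids & mw$consumer_id %in% ids
  mw <- mw[keep, , drop = FALSE]

  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(mw)) {
    p <- interaction_probability(
      mw$link_type, roles[mw$resource_id],
      ifelse(is.na(n_rel[mw$resource_id]), 0, n_rel[mw$resource_id]),
      ifelse(is.na(n_rel[mw$consumer_id]), 0, n_rel[mw$consumer_id]),
      scalars)
    A[cbind(mw$resource_id, mw$consumer_id)] <- p
  }
  structure(list(plot_id = plot_id, time_period = time_period,
                 nodes = ids, roles = roles, A = A,
                 sown_richness = smp$sown_richness,
                 block_id = smp$block_id),
            class = "prob_web")
}

#' @exportS3Method base::print
print.prob_web <- function(x, ...) {
  cat(sprintf("<prob_web %s/%s> %d nodes, %d supported links, sum(A)=%.1f\n",
              x$plot_id, x$time_period, length(x$nodes), sum(x$A > 0),
              sum(x$A)))
  invisible(x)
}

.new_binary_web <- function(pweb, edges, iteration = NA_integer_,
                            prune = TRUE) {
  nodes <- pweb$nodes
  if (prune) {
    used <- unique(c(edges$from, edges$to))
    nodes <- nodes[nodes %in% used]
  }
  structure(list(plot_id = pweb$plot_id, time_period = pweb$time_period,
                 iteration = iteration, nodes = nodes,
                 roles = pweb$roles[nodes], edges = edges),
            class = "binary_web")
}

#' Sample one binary food web
#'
#' Each supported link is included independently with its interaction
#' probability; nodes left with total degree zero are omitted.
#'
#' @param pweb a `prob_web`.
#' @param seed optional integer seed for reproducibility.
#' @param iteration iteration index stored on the result.
#' @return a `binary_web` with an edge table (`from` = resource,
#'   `to` = consumer).
#' @export
sample_binary_web <- function(pweb, seed = NULL, iteration = NA_integer_) {
  stopifnot(inherits(pweb, "prob_web"))
  if (!is.null(seed)) set.seed(seed)
  idx <- which(pweb$A > 0, arr.ind = TRUE)
  p <- pweb$A[idx]
  keep <- runif(length(p)) < p
  edges <- data.frame(from = rownames(pweb$A)[idx[keep, 1]],
                      to = colnames(pweb$A)[idx[keep, 2]],
                      stringsAsFactors = FALSE)
  .new_binary_web(pweb, edges, iteration)
}

#' @exportS3Method base::print
print.binary_web <- function(x, ...) {
  cat(sprintf("<binary_web %s/%s it=%s> %d nodes, %d links\n",
              x$plot_id, x$time_period, x$iteration, length(x$nodes),
              nrow(x$edges)))
  invisible(x)
}

#' Consumer sub-web
#'
#' Removes plant and static-resource nodes together with their incident
#' links, then drops consumers left with degree zero. Motifs counted on the
#' result are the free-floating motifs of the parent web.
#'
#' @param bweb a `binary_web`.
#' @return a `binary_web` over consumers only.
#' @export
consumer_subweb <- function(bweb) {
  stopifnot(inherits(bweb, "binary_web"))
  cons <- bweb$nodes[bweb$roles == "consumer"]
  e <- bweb$edges[bweb$edges$from %in% cons & bweb$edges$to %in% cons, ,
                  drop = FALSE]
  used <- unique(c(e$from, e$to))
  structure(list(plot_id = bweb$plot_id, time_period = bweb$time_period,
                 iteration = bweb$iteration, nodes = cons[cons %in% used],
                 roles = bweb$roles[cons[cons %in% used]], edges = e),
            class = "binary_web")
}

#' Generality of each consumer in a binary web
#'
#' Number of resource taxa each consumer feeds on (in-links of the consumer).
#'
#' @param bweb a `binary_web`.
#' @param guild optional guild filter (e.g. `"omnivore"`).
#' @param nodes node table used to look up guilds (required with `guild`).
#' @return named integer vector over consumers.
#' @export
generality <- function(bweb, guild = NULL, nodes = NULL) {
  cons <- bweb$nodes[bweb$roles == "consumer"]
  if (!is.null(guild)) {
    stopifnot(!is.null(nodes))
    g <- setNames(nodes$guild, nodes$id)[cons]
    cons <- cons[g == guild]
  }
  tab <- table(factor(bweb$edges$to, levels = cons))
  setNames(as.integer(tab), cons)
}

#' Calibrate the encounter scalars
#'
#' Reproduces the calibration procedure: over a grid of `(alpha, beta)`
#' pairs, build and sample webs for the highest-diversity plots and pick the
#' pair whose median omnivore generality (averaged over sampled webs) is
#' closest to the target (ca. 30 resource taxa, matching the mean realised
#' plant richness of ca. 33 species on 60-species plots). Ties are broken
#' towards smaller `alpha`, then smaller `beta`.
#'
#' @param comm a `motifweb_community` containing omnivores.
#' @param grid data frame with columns `alpha`, `beta`.
#' @param target_generality target median omnivore generality (default 30).
#' @param iterations sampled webs per plot-period (default 3; the criterion
#'   is a median, so few samples suffice).
#' @param plot_ids plots to calibrate on; defaults to those with the highest
#'   sown richness.
#' @param seed integer seed.
#' @return the selected [scalar_config()], with the evaluated grid attached
#'   as attribute `"grid"`.
#' @export
calibrate_scalars <- function(comm, grid, target_generality = 30,
                              iterations = 3, plot_ids = NULL, seed = 1) {
  if (!nrow(grid)) stop("empty candidate grid", call. = FALSE)
  if (!any(comm$nodes$guild == "omnivore"))
    stop("no omnivores in the species pool; cannot calibrate", call. = FALSE)
  if (is.null(plot_ids)) {
    top <- max(comm$design$sown_richness)
    plot_ids <- comm$design$plot_id[comm$design$sown_richness == top]
  }
  periods <- unique(comm$samples$time_period)
  grid <- grid[order(grid$alpha, grid$beta), , drop = FALSE]
  grid$median_generality <- NA_real_
  for (g in seq_len(nrow(grid))) {
    sc <- scalar_config(grid$alpha[g], grid$beta[g])
    meds <- c()
    for (pl in plot_ids) for (pd in periods) {
      pweb <- build_probabilistic_web(comm, pl, pd, sc)
      for (it in seq_len(iterations)) {
        bw <- sample_binary_web(pweb, seed = derive_seed(seed, pl, pd, g, it))
        gen <- generality(bw, guild = "omnivore", nodes = comm$nodes)
        if (length(gen)) meds <- c(meds, median(gen))
      }
    }
    grid$median_generality[g] <- if (length(meds)) mean(meds) else NA_real_
  }
  best <- which.min(abs(grid$median_generality - target_generality))
  out <- scalar_config(grid$alpha[best], grid$beta[best])
  attr(out, "grid") <- grid
  out
}

#' Diversity-scaled predator-prey scalar
#'
#' Sensitivity scenario in which the density-dependent probability of
#' predator-prey encounters declines with plant diversity (e.g. because
#' structurally complex vegetation provides prey refugia): `beta` is scaled
#' linearly from its base value at sown richness 1 down to
#' `(1 - strength) * beta` at sown richness 60; `alpha` is unchanged.
#'
#' @param base a [scalar_config()].
#' @param sown_richness sown plant richness of the plot.
#' @param strength scenario strength in `[0,1]`; 0 disables the scaling.
#' @export
diversity_scaled_scalars <- function(base, sown_richness, strength) {
  stopifnot(inherits(base, "scalar_config"),
            strength >= 0, strength <= 1, sown_richness >= 1)
  frac <- (min(sown_richness, 60) - 1) / 59
  scalar_config(base$alpha, base$beta * (1 - strength * frac))
}
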