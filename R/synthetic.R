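# Synthetic community generator: emulates the structure of a grassland
# biodiversity experiment (sown richness gradient over 80 plots in 4 blocks,
# 4 sampling periods) with a trait-rule metaweb over a plant pool, six
# ubiquitous static basal resources, and a guild-structured arthropod pool,
# so the whole analysis pipeline runs without field data.

#' Generator configuration
#'
#' Defaults emulate the experiment the pipeline was designed around: 60
#' plant species in four functional groups sown at richness levels
#' 1/2/4/8/16/60 over 80 plots in 4 blocks and 4 time periods, a consumer
#' pool of ~400 species partitioned into detritivore / herbivore / omnivore
#' / predator guilds, and a metaweb built from diet rules (family-level
#' oligophagy with a monophagous fraction for herbivores; body-size-ratio
#' and stratum rules for predators).
#'
#' @param global_seed master seed; every downstream draw derives from it.
#' @param n_plants plant pool size.
#' @param plant_fg named sizes of the four plant functional groups (must sum
#'   to `n_plants`).
#' @param n_plant_families number of plant families diets are keyed to.
#' @param n_consumers consumer pool size.
#' @param guild_mix fractions of consumers per guild (sums to 1).
#' @param herbivore_diet fractions of herbivores that are monophagous
#'   (single plant, link type 1), oligophagous (one family, type 2) or
#'   generalist (one functional group, type 3); sums to 1.
#' @param body_length_meanlog,body_length_sdlog per-guild lognormal body
#'   length parameters (mm).
#' @param stratum_prob per-guild probabilities over (ground, herb, both).
#' @param predator_size_window admissible prey/predator body-length ratio.
#' @param colonization_p_max per-guild ceiling of the presence probability.
#' @param colonization_baseline per-guild resource-independent floor of the
#'   presence probability (as a fraction of the ceiling); nonzero for
#'   omnivores and predators, whose vagile taxa colonise plots partly
#'   independently of local diet availability, which attenuates the
#'   richness response up the trophic hierarchy.
#' @param colonization_steepness per-guild exponent linking presence
#'   probability to the fraction of the consumer's metaweb diet present on
#'   the plot; larger values couple occurrence more tightly to resource
#'   availability and hence steepen the diversity cascade for that guild.
#' @param abundance_meanlog,abundance_sdlog lognormal parameters for
#'   consumer counts.
#' @param cover_decay geometric rank-abundance decay of plant cover.
#' @param total_cover vegetated fraction of a plot (covers sum to this).
#' @param richness_levels sown richness design levels.
#' @param plots_per_level plots per level (sums to 80).
#' @param n_blocks,n_periods experimental blocks and sampling periods.
#' @param realized_richness_target mean realised plant richness on plots
#'   sown with the full pool (ca. 33 of 60), controlling the saturating
#'   thinning of sown richness.
#' @return a `generator_config` list.
#' @export
generator_config <- function(
    global_seed = 1L,
    n_plants = 60L,
    plant_fg = c(grass = 16L, small_herb = 12L, tall_herb = 20L, legume = 12L),
    n_plant_families = 15L,
    n_consumers = 400L,
    guild_mix = c(detritivore = 0.15, herbivore = 0.38, omnivore = 0.12,
                  predator = 0.35),
    herbivore_diet = c(monophagous = 0.2, oligophagous = 0.5,
                       generalist = 0.3),
    body_length_meanlog = c(detritivore = log(6), herbivore = log(4),
                            omnivore = log(6), predator = log(6)),
    body_length_sdlog = 0.6,
    stratum_prob = list(detritivore = c(ground = 0.8, herb = 0.1, both = 0.1),
                        herbivore = c(ground = 0.15, herb = 0.7, both = 0.15),
                        omnivore = c(ground = 0.4, herb = 0.3, both = 0.3),
                        predator = c(ground = 0.45, herb = 0.35, both = 0.2)),
    predator_size_window = c(0.15, 1.1),
    colonization_p_max = c(detritivore = 0.5, herbivore = 0.75,
                           omnivore = 0.6, predator = 0.55),
    colonization_baseline = c(detritivore = 0, herbivore = 0,
                              omnivore = 0.2, predator = 0.3),
    colonization_steepness = c(detritivore = 1, herbivore = 1,
                               omnivore = 2, predator = 2),
    abundance_meanlog = log(4),
    abundance_sdlog = 1,
    cover_decay = 0.85,
    total_cover = 0.9,
    richness_levels = c(1L, 2L, 4L, 8L, 16L, 60L),
    plots_per_level = c(16L, 16L, 16L, 16L, 12L, 4L),
    n_blocks = 4L,
    n_periods = 4L,
    realized_richness_target = 33) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$guild_mix) - 1) > 1e-8)
    stop("guild_mix fractions must sum to 1", call. = FALSE)
  if (abs(sum(cfg$herbivore_diet) - 1) > 1e-8)
    stop("herbivore_diet fractions must sum to 1", call. = FALSE)
  if (sum(cfg$plant_fg) != cfg$n_plants)
    stop("plant functional group sizes must sum to n_plants", call. = FALSE)
  if (sum(cfg$plots_per_level) != 80L || length(cfg$plots_per_level) !=
        length(cfg$richness_levels))
    stop("plots_per_level must allocate 80 plots over the richness levels",
         call. = FALSE)
  if (cfg$predator_size_window[1] >= cfg$predator_size_window[2] ||
      any(cfg$predator_size_window <= 0))
    stop("predator_size_window must be an increasing positive pair",
         call. = FALSE)
  structure(cfg, class = "generator_config")
}

.static_ids <- c("detritus", "moss", "algae", "fungi", "dung", "carrion")

#' Generate the species pool and trait-rule metaweb
#'
#' Plants are assigned to families and functional groups. Herbivores receive
#' plant links by diet breadth (monophagous: one plant, link type 1;
#' oligophagous: all plants of one family, type 2; generalist: all plants of
#' one functional group, type 3). Detritivores feed on static resources
#' (type 2 when specific to one resource, else type 3). Predators feed on
#' consumers whose body length falls in the size window and whose stratum is
#' compatible (type 4 when either party uses both strata, type 5 when the
#' stratum rule also binds). Omnivores receive a plant-side diet plus
#' predator-style animal links. No self-links; plants never consume.
#'
#' @param cfg a [generator_config()].
#' @return list with the node table and the metaweb link table.
#' @export
generate_pool <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(derive_seed(cfg$global_seed, "pool"))

  plants <- data.frame(
    id = sprintf("P%03d", seq_len(cfg$n_plants)),
    role = "plant", guild = "none", stratum = "none",
    body_length_mm = NA_real_, stringsAsFactors = FALSE)
  fg <- rep(names(cfg$plant_fg), cfg$plant_fg)
  fam <- sample(rep_len(seq_len(cfg$n_plant_families), cfg$n_plants))
  statics <- data.frame(id = .static_ids, role = "static_resource",
                        guild = "none", stratum = "none",
                        body_length_mm = NA_real_, stringsAsFactors = FALSE)

  n_g <- round(cfg$guild_mix * cfg$n_consumers)
  n_g[length(n_g)] <- cfg$n_consumers - sum(n_g[-length(n_g)])
  guild <- rep(names(n_g), n_g)
  strat <- vapply(guild, function(g)
    sample(names(cfg$stratum_prob[[g]]), 1, prob = cfg$stratum_prob[[g]]), "")
  consumers <- data.frame(
    id = sprintf("C%03d", seq_len(cfg$n_consumers)),
    role = "consumer", guild = guild, stratum = unname(strat),
    body_length_mm = rlnorm(cfg$n_consumers,
                            cfg$body_length_meanlog[guild],
                            cfg$body_length_sdlog),
    stringsAsFactors = FALSE)
  nodes <- rbind(plants, statics, consumers)

  links <- list()
  add <- function(res, con, type) {
    if (length(res))
      links[[length(links) + 1]] <<- data.frame(
        resource_id = res, consumer_id = con, link_type = type,
        stringsAsFactors = FALSE)
  }

  plant_side <- function(con_id, breadth) {
    switch(breadth,
      monophagous = add(sample(plants$id, 1), con_id, 1L),
      oligophagous = add(plants$id[fam == sample(cfg$n_plant_families, 1)],
                         con_id, 2L),
      generalist = add(plants$id[fg == sample(names(cfg$plant_fg), 1)],
                       con_id, 3L))
  }
  animal_side <- function(i) {
    L <- consumers$body_length_mm[i]
    win <- cfg$predator_size_window * L
    ok_size <- consumers$body_length_mm >= win[1] &
               consumers$body_length_mm <= win[2]
    s <- consumers$stratum[i]
    ok_strat <- s == "both" | consumers$stratum == "both" |
                consumers$stratum == s
    prey <- which(ok_size & ok_strat & seq_len(nrow(consumers)) != i)
    if (length(prey)) {
      binding <- s != "both" & consumers$stratum[prey] != "both"
      add(consumers$id[prey][!binding], consumers$id[i], 4L)
      add(consumers$id[prey][binding], consumers$id[i], 5L)
    }
  }

  for (i in seq_len(nrow(consumers))) {
    g <- consumers$guild[i]
    if (g == "herbivore") {
      plant_side(consumers$id[i],
                 sample(names(cfg$herbivore_diet), 1,
                        prob = cfg$herbivore_diet))
    } else if (g == "detritivore") {
      k <- sample(4, 1)
      add(sample(.static_ids, k), consumers$id[i], if (k == 1) 2L else 3L)
    } else if (g == "omnivore") {
      plant_side(consumers$id[i], "generalist")
      add(sample(.static_ids, sample(2:3, 1)), consumers$id[i], 3L)
      animal_side(i)
    } else {
      animal_side(i)
    }
  }
  metaweb <- unique(do.call(rbind, links))
  if (any(guild == "predator") && !any(metaweb$link_type %in% 4:5))
    stop("infeasible configuration: the predator size window excludes all prey",
         call. = FALSE)
  list(nodes = nodes, metaweb = metaweb)
}

.persistence_prob <- function(sown, cfg) {
  lam <- -log(cfg$realized_richness_target / 60) / log2(60)
  exp(-lam * log2(sown))
}

#' Generate the experimental design and plot samples
#'
#' Allocates the sown richness levels over 80 plots in 4 blocks, thins sown
#' plant sets to realised sets with a saturating persistence probability
#' (calibrated so mean realised richness at sown 60 matches the configured
#' target), assigns geometric-series relative covers, and colonises plots
#' with consumers whose presence probability rises with the fraction of
#' their metaweb diet present (detritivores, then herbivores, then
#' omnivores, then predators, so higher trophic levels respond to realised
#' prey). Counts of present consumers are lognormal.
#'
#' @param cfg a [generator_config()].
#' @param pool result of [generate_pool()].
#' @return a validated `motifweb_community`.
#' @export
generate_design <- function(cfg, pool) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(derive_seed(cfg$global_seed, "design"))
  nodes <- pool$nodes
  plants <- nodes$id[nodes$role == "plant"]
  consumers <- nodes[nodes$role == "consumer", ]

  # per-consumer metaweb diet
  diet <- split(pool$metaweb$resource_id, pool$metaweb$consumer_id)

  # allocation of levels to plots, dealt round-robin over blocks so each
  # block spans the full gradient
  lv_all <- rep(cfg$richness_levels, cfg$plots_per_level)
  blocks <- rep_len(sprintf("B%d", seq_len(cfg$n_blocks)), 80)
  design <- data.frame(plot_id = sprintf("plot%02d", 1:80),
                       block_id = blocks,
                       sown_richness = as.integer(lv_all),
                       stringsAsFactors = FALSE)

  sown_sets <- lapply(design$sown_richness, function(k)
    if (k >= length(plants)) plants else sample(plants, k))

  periods <- sprintf("T%d", seq_len(cfg$n_periods))
  recs <- vector("list", 80 * cfg$n_periods)
  r <- 0
  for (p in 1:80) {
    sown <- sown_sets[[p]]
    keep_p <- .persistence_prob(design$sown_richness[p], cfg)
    for (pd in periods) {
      set.seed(derive_seed(cfg$global_seed, design$plot_id[p], pd, "sample"))
      realized <- sown[runif(length(sown)) < keep_p]
      if (!length(realized)) realized <- sample(sown, 1)
      shares <- cfg$cover_decay^(seq_along(realized) - 1)
      shares <- sample(shares / sum(shares) * cfg$total_cover)
      present <- c(realized, .static_ids)

      rows <- list(data.frame(plot_id = design$plot_id[p], time_period = pd,
                              node_id = realized, value = shares,
                              value_kind = "cover",
                              stringsAsFactors = FALSE))
      # guild-ordered colonisation
      for (g in c("detritivore", "herbivore", "omnivore", "predator")) {
        gi <- which(consumers$guild == g)
        d <- diet[consumers$id[gi]]
        f <- vapply(d, function(res)
          if (is.null(res) || !length(res)) 0
          else mean(res %in% present), 0)
        b0 <- cfg$colonization_baseline[g]
        pr <- cfg$colonization_p_max[g] *
          (b0 + (1 - b0) * f^cfg$colonization_steepness[g])
        here <- gi[runif(length(gi)) < pr]
        if (length(here)) {
          cnt <- pmax(1, round(rlnorm(length(here), cfg$abundance_meanlog,
                                      cfg$abundance_sdlog)))
          rows[[length(rows) + 1]] <- data.frame(
            plot_id = design$plot_id[p], time_period = pd,
            node_id = consumers$id[here], value = cnt,
            value_kind = "count", stringsAsFactors = FALSE)
          present <- c(present, consumers$id[here])
        }
      }
      r <- r + 1
      recs[[r]] <- do.call(rbind, rows)
    }
  }
  community(nodes, pool$metaweb, design, do.call(rbind, recs))
}

#' Generate a complete synthetic community
#'
#' Convenience wrapper: [generate_pool()] then [generate_design()].
#'
#' @param cfg a [generator_config()]; defaults to the standard design.
#' @return a `motifweb_community`.
#' @export
generate_community <- function(cfg = generator_config()) {
  pool <- generate_pool(cfg)
  generate_design(cfg, pool)
}
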