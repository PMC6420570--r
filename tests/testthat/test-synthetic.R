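test_that("pool generation enforces the configured guild mix and diet rules", {
  cfg <- generator_config(global_seed = 2, n_consumers = 120L)
  pool <- generate_pool(cfg)
  cons <- pool$nodes[pool$nodes$role == "consumer", ]
  expect_equal(nrow(cons), 120)
  expect_equal(as.integer(table(cons$guild)[names(cfg$guild_mix)]),
               as.integer(round(cfg$guild_mix * 120)))
  expect_equal(sum(pool$nodes$role == "plant"), cfg$n_plants)
  expect_equal(sum(pool$nodes$role == "static_resource"), 6)
  # structural invariants
  expect_false(any(pool$metaweb$resource_id == pool$metaweb$consumer_id))
  role_of <- setNames(pool$nodes$role, pool$nodes$id)
  expect_true(all(role_of[pool$metaweb$consumer_id] == "consumer"))
})

test_that("every metaweb link re-validates against its generative rule", {
  cfg <- generator_config(global_seed = 4, n_consumers = 150L)
  pool <- generate_pool(cfg)
  nd <- pool$nodes
  role_of <- setNames(nd$role, nd$id)
  guild_of <- setNames(nd$guild, nd$id)
  strat_of <- setNames(nd$stratum, nd$id)
  len_of <- setNames(nd$body_length_mm, nd$id)
  mw <- pool$metaweb
  basal_types <- mw$link_type %in% 1:3
  # types 1-3 run from basal resources to plant/detritus feeders
  expect_true(all(role_of[mw$resource_id[basal_types]] %in%
                    c("plant", "static_resource")))
  expect_true(all(guild_of[mw$consumer_id[basal_types]] %in%
                    c("herbivore", "omnivore", "detritivore")))
  # type 1 is monophagy: one plant link and no other plant link
  t1 <- mw[mw$link_type == 1, ]
  expect_true(all(role_of[t1$resource_id] == "plant"))
  expect_true(all(table(t1$consumer_id) == 1))
  # predatory links obey the body-size window and stratum compatibility
  t45 <- mw[mw$link_type %in% 4:5, ]
  expect_true(all(role_of[t45$resource_id] == "consumer"))
  ratio <- len_of[t45$resource_id] / len_of[t45$consumer_id]
  expect_true(all(ratio >= cfg$predator_size_window[1] - 1e-12))
  expect_true(all(ratio <= cfg$predator_size_window[2] + 1e-12))
  sr <- strat_of[t45$resource_id]
  sc <- strat_of[t45$consumer_id]
  expect_true(all(sr == "both" | sc == "both" | sr == sc))
  # type 5 is the stratum-constrained subset
  t5 <- mw[mw$link_type == 5, ]
  expect_true(all(strat_of[t5$resource_id] != "both" &
                    strat_of[t5$consumer_id] != "both"))
})

test_that("pools without animal feeders contain no trait-based links", {
  cfg <- generator_config(
    global_seed = 3, n_consumers = 40L,
    guild_mix = c(detritivore = 0.5, herbivore = 0.5, omnivore = 0,
                  predator = 0))
  pool <- generate_pool(cfg)
  expect_false(any(pool$metaweb$link_type %in% 4:5))
  # all-monophagous herbivores: exactly one type-1 link each
  cfg2 <- generator_config(
    global_seed = 3, n_consumers = 30L,
    guild_mix = c(detritivore = 0, herbivore = 1, omnivore = 0,
                  predator = 0),
    herbivore_diet = c(monophagous = 1, oligophagous = 0, generalist = 0))
  pool2 <- generate_pool(cfg2)
  expect_equal(nrow(pool2$metaweb), 30)
  expect_true(all(pool2$metaweb$link_type == 1))
})

test_that("the design reproduces the experimental structure", {
  cfg <- generator_config(global_seed = 6, n_consumers = 80L)
  comm <- generate_community(cfg)
  expect_equal(nrow(comm$design), 80)
  expect_equal(sort(unique(comm$design$sown_richness)),
               c(1, 2, 4, 8, 16, 60))
  expect_equal(as.integer(table(comm$design$sown_richness)),
               c(16L, 16L, 16L, 16L, 12L, 4L))
  expect_length(unique(comm$design$block_id), 4)
  recs <- unique(comm$samples[c("plot_id", "time_period")])
  expect_equal(nrow(recs), 320)
  # realised richness never exceeds sown richness
  cov <- comm$samples[comm$samples$value_kind == "cover", ]
  realized <- aggregate(node_id ~ plot_id + time_period, cov, length)
  realized <- merge(realized, comm$design)
  expect_true(all(realized$node_id <= realized$sown_richness))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(global_seed = 12, n_consumers = 60L)
  c1 <- generate_community(cfg)
  c2 <- generate_community(cfg)
  expect_identical(c1, c2)
  d1 <- file.path(tempdir(), "gen1"); d2 <- file.path(tempdir(), "gen2")
  write_community(c1, d1); write_community(c2, d2)
  for (f in c("traits.tsv", "metaweb.tsv", "abundance.tsv", "design.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("the diversity cascade attenuates up the trophic hierarchy", {
  herb_slopes <- pred_slopes <- c()
  for (sd in 1:3) {
    comm <- generate_community(generator_config(global_seed = sd,
                                                n_consumers = 150L))
    s <- comm$samples[comm$samples$value_kind == "count", ]
    g <- setNames(comm$nodes$guild, comm$nodes$id)
    s$guild <- g[s$node_id]
    rich <- aggregate(node_id ~ plot_id + time_period + guild, s, length)
    rich <- merge(rich, comm$design)
    sl <- function(gu) {
      d <- rich[rich$guild == gu, ]
      unname(coef(lm(node_id ~ log2(sown_richness), d))[2])
    }
    herb_slopes <- c(herb_slopes, sl("herbivore"))
    pred_slopes <- c(pred_slopes, sl("predator"))
    # consumer richness is non-decreasing across richness levels on average
    tot <- aggregate(node_id ~ plot_id + time_period, s, length)
    tot <- merge(tot, comm$design)
    mt <- tapply(tot$node_id, tot$sown_richness, mean)
    expect_true(all(diff(mt) > -2))  # monotone up to sampling noise
    expect_gt(mt[length(mt)], mt[1])
  }
  expect_true(all(herb_slopes > pred_slopes))
  expect_true(all(pred_slopes > 0))
})
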