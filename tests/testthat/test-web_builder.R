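test_that("interaction probabilities follow the link-type rules", {
  sc <- scalar_config(10, 1000)
  # literature-specific links: encounter certain
  expect_equal(interaction_probability(1, "plant", 0.01, 0.01, sc), 1)
  # types 2-3 with consumer or static resource: certain
  expect_equal(interaction_probability(2, "consumer", 0.2, 0.1, sc), 1)
  expect_equal(interaction_probability(3, "static_resource", 0, 0, sc), 1)
  # types 2-3 with plant resource: alpha-scaled product
  expect_equal(interaction_probability(3, "plant", 0.2, 0.05, sc), 0.1)
  # types 4-5: beta-scaled, clipped at 1
  expect_equal(interaction_probability(4, "consumer", 0.1, 0.1, sc), 1)
  sc2 <- scalar_config(10, 5)
  expect_equal(interaction_probability(5, "consumer", 0.2, 0.1, sc2), 0.1)
  expect_error(interaction_probability(6, "plant", 0.1, 0.1, sc), "link type")
  expect_error(interaction_probability(2, "plant", 1.5, 0.1, sc), "\\[0,1\\]")
})

test_that("probability web restricts to co-occurring species", {
  comm <- tiny_community()
  sc <- scalar_config(10, 100)
  pw <- build_probabilistic_web(comm, "plotB", "T1", sc)
  # det1 and omn1 have zero count on plotB: excluded
  expect_false(any(c("det1", "omn1") %in% pw$nodes))
  # static resources always included
  expect_true(all(c("detritus", "moss") %in% pw$nodes))
  # support of A equals metaweb restricted to co-occurring nodes
  mw <- comm$metaweb
  co <- mw[mw$resource_id %in% pw$nodes & mw$consumer_id %in% pw$nodes, ]
  sup <- which(pw$A > 0, arr.ind = TRUE)
  got <- sort(paste(rownames(pw$A)[sup[, 1]], colnames(pw$A)[sup[, 2]]))
  expect_equal(got, sort(paste(co$resource_id, co$consumer_id)))
  # monophagous type-1 link has probability exactly 1
  expect_equal(pw$A["p1", "herb1"], 1)
  expect_error(build_probabilistic_web(comm, "plotA", "T9", sc),
               "degenerate")
})

test_that("relative abundances are normalised within strata", {
  comm <- tiny_community()
  smp <- plot_sample(comm, "plotA", "T1")
  n <- relative_abundances(smp, comm$nodes)
  expect_equal(unname(n["p1"]), 1)  # single plant
  # ground total = det1 + both species; herb total = herb1 + both species
  g_tot <- 5 + 2 + 3
  h_tot <- 10 + 2 + 3
  expect_equal(unname(n["det1"]), 5 / g_tot)
  expect_equal(unname(n["herb1"]), 10 / h_tot)
  expect_equal(unname(n["omn1"]), mean(c(2 / g_tot, 2 / h_tot)))
})

test_that("binary sampling matches its probabilities", {
  ids <- c("a", "b", "c")
  A <- matrix(0, 3, 3, dimnames = list(ids, ids))
  A["a", "b"] <- 1
  A["b", "c"] <- 1
  pw <- make_pweb(A)
  bw <- sample_binary_web(pw, seed = 1)
  expect_equal(nrow(bw$edges), 2)
  expect_setequal(bw$nodes, ids)

  # all-zero support: empty web
  pw0 <- make_pweb(matrix(0, 3, 3, dimnames = list(ids, ids)))
  bw0 <- sample_binary_web(pw0, seed = 1)
  expect_equal(nrow(bw0$edges), 0)
  expect_length(bw0$nodes, 0)

  # single edge with p = 0.5: inclusion frequency within 3 SE
  A2 <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  A2["x", "y"] <- 0.5
  pw2 <- make_pweb(A2)
  set.seed(99)
  hits <- vapply(seq_len(10000),
                 function(i) nrow(sample_binary_web(pw2)$edges), 0)
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(mean(hits) - 0.5), 3 * se)
})

test_that("expected edge count equals the sum of probabilities", {
  set.seed(7)
  ids <- sprintf("n%02d", 1:12)
  A <- matrix(runif(144) * (runif(144) < 0.3), 12, 12,
              dimnames = list(ids, ids))
  diag(A) <- 0
  pw <- make_pweb(A)
  draws <- vapply(seq_len(1000),
                  function(i) nrow(sample_binary_web(pw)$edges), 0)
  se <- sqrt(sum(A * (1 - A)) / 1000)
  expect_lt(abs(mean(draws) - sum(A)), 3 * se)
})

test_that("degree-zero pruning is idempotent and saturation fills support", {
  comm <- tiny_community()
  # alpha, beta -> large: every supported link certain
  pw <- build_probabilistic_web(comm, "plotA", "T1", scalar_config(1e9, 1e9))
  sup <- sum(pw$A > 0)
  expect_true(all(pw$A[pw$A > 0] == 1))
  bw <- sample_binary_web(pw, seed = 1)
  expect_equal(nrow(bw$edges), sup)
  # pruning again changes nothing
  bw2 <- motifweb:::.new_binary_web(pw, bw$edges)
  expect_equal(sort(bw2$nodes), sort(bw$nodes))
})

test_that("consumer sub-web removes basal nodes and is idempotent", {
  roles <- c(P = "plant", H = "consumer", C = "consumer", D = "consumer")
  bw <- make_web(data.frame(from = c("P", "H", "C"), to = c("H", "C", "D")),
                 roles = roles)
  sw <- consumer_subweb(bw)
  expect_setequal(sw$nodes, c("H", "C", "D"))
  expect_equal(nrow(sw$edges), 2)
  sw2 <- consumer_subweb(sw)
  expect_equal(sw2$edges, sw$edges)
  expect_setequal(sw2$nodes, sw$nodes)
  # only basal nodes: empty sub-web
  bw2 <- make_web(data.frame(from = "P1", to = "H1"),
                  roles = c(P1 = "plant", H1 = "consumer"))
  swb <- consumer_subweb(bw2)
  expect_equal(nrow(swb$edges), 0)
  # edge count equals consumer-to-consumer edges of the parent
  set.seed(3)
  w <- random_web(15, 0.2)
  w$roles[1:5] <- "plant"
  sw3 <- consumer_subweb(w)
  cons <- names(w$roles)[w$roles == "consumer"]
  expect_equal(nrow(sw3$edges),
               sum(w$edges$from %in% cons & w$edges$to %in% cons))
})

test_that("scalar calibration selects the grid point nearest the target", {
  cfg <- generator_config(global_seed = 11, n_consumers = 60L,
                          plots_per_level = c(15L, 15L, 15L, 15L, 15L, 5L))
  comm <- generate_community(cfg)
  one <- calibrate_scalars(comm, data.frame(alpha = 5, beta = 5),
                           iterations = 1, seed = 2)
  expect_equal(one$alpha, 5)
  expect_equal(one$beta, 5)
  grid <- data.frame(alpha = c(2, 2000), beta = c(2, 2000))
  sc <- calibrate_scalars(comm, grid, target_generality = 1e6,
                          iterations = 1, seed = 2)
  g <- attr(sc, "grid")
  # generality is monotone in the scalars, so the huge target picks the
  # largest pair
  expect_true(diff(g$median_generality) > 0)
  expect_equal(sc$alpha, 2000)
  nodes_noomn <- comm$nodes
  nodes_noomn$guild[nodes_noomn$guild == "omnivore"] <- "predator"
  comm2 <- community(nodes_noomn, comm$metaweb, comm$design, comm$samples)
  expect_error(calibrate_scalars(comm2, grid), "omnivore")
})

test_that("diversity-scaled beta interpolates linearly in richness", {
  base <- scalar_config(10, 100)
  expect_equal(diversity_scaled_scalars(base, 60, 0)$beta, 100)
  expect_equal(diversity_scaled_scalars(base, 1, 0.7)$beta, 100)
  expect_equal(diversity_scaled_scalars(base, 60, 0.5)$beta, 50)
  mid <- diversity_scaled_scalars(base, 16, 0.5)
  expect_equal(mid$beta, 100 * (1 - 0.5 * 15 / 59))
  expect_equal(mid$alpha, 10)
})
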