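# Diversity-gradient models: linear mixed models of motif counts and
# normalised scores against sown plant richness, plus the descriptive
# summaries (motif shares, grounded vs free-floating fractions).

#' Mixed-model richness trend for one response
#'
#' Fits `response ~ log2(sown_richness)` with random intercepts for time
#' period and for plot nested in block, the structure matching a design of
#' 4 periods x 80 plots in 4 blocks (n = 320). Counts should be
#' `log(x + 1)`-transformed via `log_counts = TRUE`; normalised scores are
#' analysed untransformed. P-values use the Satterthwaite approximation; on
#' a singular or failed fit the random structure is downgraded stepwise
#' (with a warning), ending at ordinary least squares.
#'
#' @param data data frame with columns `sown_richness`, `time_period`,
#'   `block_id`, `plot_id` and the response.
#' @param response name of the response column.
#' @param log_counts if TRUE the response is `log(x + 1)`-transformed.
#' @param richness_transform `"log2"` (default, the levels form a doubling
#'   series) or `"linear"`.
#' @return one-row data frame: slope, SE, df, two-tailed p, n, the random
#'   structure actually used, and the response name.
#' @export
fit_richness_trend <- function(data, response, log_counts = FALSE,
                               richness_transform = c("log2", "linear")) {
  richness_transform <- match.arg(richness_transform)
  if (length(unique(data$sown_richness)) < 2)
    stop("at least two richness levels are required", call. = FALSE)
  d <- data.frame(
    y = if (log_counts) log(data[[response]] + 1) else data[[response]],
    x = if (richness_transform == "log2") log2(data$sown_richness)
        else as.numeric(data$sown_richness),
    time_period = factor(data$time_period),
    block_id = factor(data$block_id),
    plot_id = factor(data$plot_id))
  d <- d[complete.cases(d), ]

  structures <- c("(1 | time_period) + (1 | block_id / plot_id)",
                  "(1 | time_period) + (1 | plot_id)",
                  "(1 | plot_id)")
  fit <- NULL; used <- NA_character_
  for (s in structures) {
    f <- try(suppressMessages(lmerTest::lmer(
      as.formula(paste("y ~ x +", s)), data = d,
      control = lme4::lmerControl(check.conv.singular =
        lme4::.makeCC(action = "ignore", tol = 1e-4)))), silent = TRUE)
    if (inherits(f, "try-error")) next
    if (lme4::isSingular(f, tol = 1e-4)) {
      if (s == structures[1])
        warning("singular fit for '", response,
                "'; downgrading the random structure", call. = FALSE)
      next
    }
    fit <- f; used <- s; break
  }
  if (is.null(fit)) {
    warning("no non-singular mixed model for '", response,
            "'; falling back to OLS", call. = FALSE)
    f <- stats::lm(y ~ x, data = d)
    cf <- summary(f)$coefficients
    return(data.frame(response = response, slope = cf["x", 1],
                      se = cf["x", 2], df = f$df.residual,
                      p_value = cf["x", 4], n = nrow(d),
                      random_structure = "none (OLS)", method = "OLS t-test",
                      stringsAsFactors = FALSE))
  }
  cf <- stats::coef(summary(fit))
  data.frame(response = response, slope = cf["x", "Estimate"],
             se = cf["x", "Std. Error"], df = cf["x", "df"],
             p_value = cf["x", "Pr(>|t|)"], n = nrow(d),
             random_structure = used, method = "Satterthwaite",
             stringsAsFactors = FALSE)
}

#' Richness trends for all motif responses
#'
#' Runs [fit_richness_trend()] for each motif class and scope, for
#' log-transformed counts and for normalised scores. Classes whose counts
#' are zero on (nearly) every record are excluded from modelling and listed
#' in the `excluded` attribute.
#'
#' @param profiles table from [run_pipeline()] / [profile_pipeline()] joined
#'   to the design (columns `plot_id`, `time_period`, `scope`, `class`,
#'   `count_mean`, `n_mean`, `sown_richness`, `block_id`).
#' @param min_nonzero minimum number of records with a nonzero count for a
#'   class x scope to be modelled (default 20).
#' @return data frame of trend rows; skipped responses in
#'   `attr(, "excluded")`.
#' @export
fit_all_trends <- function(profiles, min_nonzero = 20) {
  out <- list(); excluded <- character(0)
  for (sc in unique(profiles$scope)) {
    for (cl in unique(profiles$class)) {
      d <- profiles[profiles$scope == sc & profiles$class == cl, ]
      tag <- paste(cl, sc, sep = ".")
      if (sum(d$count_mean > 0, na.rm = TRUE) < min_nonzero) {
        excluded <- c(excluded, tag)
        next
      }
      for (resp in c("count_mean", "n_mean")) {
        tr <- fit_richness_trend(d, resp, log_counts = resp == "count_mean")
        tr$response <- paste(tag, if (resp == "count_mean") "log_count"
                             else "n_score", sep = ".")
        tr$class <- cl; tr$scope <- sc
        tr$measure <- if (resp == "count_mean") "log_count" else "n_score"
        out[[length(out) + 1]] <- tr
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

#' Descriptive summaries per richness level
#'
#' For each sown richness level: mean total motif count, the percentage of
#' all motifs in each common class (s1, s2, s4, s5) and in the "other"
#' aggregate (s3 plus all double-link classes), and per-class grounded and
#' free-floating fractions (grounded = containing a basal node, i.e. counted
#' in the full web but absent from the consumer sub-web).
#'
#' @param profiles as in [fit_all_trends()].
#' @return list of data frames: `shares` (per level x class) and `totals`
#'   (per level).
#' @export
summarize_profiles <- function(profiles) {
  full <- profiles[profiles$scope == "full", ]
  sub <- profiles[profiles$scope == "consumer_subweb", ]
  key <- c("plot_id", "time_period", "class")
  m <- merge(full[, c(key, "count_mean", "n_mean", "sown_richness")],
             sub[, c(key, "count_mean")],
             by = key, suffixes = c("_full", "_free"))

  shares <- do.call(rbind, lapply(split(m, m$sown_richness), function(d) {
    tot <- sum(d$count_mean_full)
    per_class <- do.call(rbind, lapply(split(d, d$class), function(dc) {
      cf <- sum(dc$count_mean_full); fr <- sum(dc$count_mean_free)
      data.frame(sown_richness = dc$sown_richness[1], class = dc$class[1],
                 share_pct = 100 * cf / tot,
                 grounded_fraction = if (cf > 0) (cf - fr) / cf else NA_real_,
                 free_floating_fraction = if (cf > 0) fr / cf else NA_real_,
                 n_mean = mean(dc$n_mean), stringsAsFactors = FALSE)
    }))
    per_class
  }))
  rownames(shares) <- NULL
  other <- !shares$class %in% c("s1", "s2", "s4", "s5")

  totals <- do.call(rbind, lapply(split(m, m$sown_richness), function(d) {
    nrec <- length(unique(paste(d$plot_id, d$time_period)))
    data.frame(
      sown_richness = d$sown_richness[1],
      mean_total_motifs = sum(d$count_mean_full) / nrec,
      common_share_pct = 100 * sum(d$count_mean_full[d$class %in%
        c("s1", "s2", "s4", "s5")]) / sum(d$count_mean_full),
      s4_share_pct = 100 * sum(d$count_mean_full[d$class == "s4"]) /
        sum(d$count_mean_full),
      other_share_pct = 100 * sum(d$count_mean_full[!d$class %in%
        c("s1", "s2", "s4", "s5")]) / sum(d$count_mean_full),
      stringsAsFactors = FALSE)
  }))
  rownames(totals) <- NULL
  list(shares = shares, totals = totals)
}
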