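# Motif representation relative to null models: z-scores and normalised
# significance profiles, averaged over sampling iterations.

#' Motif z-scores against a null ensemble
#'
#' `z_i = (X_i - Xbar_i) / sigma_i`, where `Xbar_i` and `sigma_i` are the
#' mean and standard deviation of motif `i` over the rewired null webs. A
#' degenerate class with `sigma_i = 0` yields 0 when the observation equals
#' the null mean; otherwise the smallest nonzero sigma of the ensemble is
#' substituted (falling back to 1 when all sigmas vanish) so the direction
#' is preserved without infinities, and the class is flagged.
#'
#' @param observed 13-vector of observed motif counts.
#' @param null_stats list with `mean` and `sd` 13-vectors (see
#'   [null_ensemble()]).
#' @return numeric 13-vector of z-scores; degenerate substitutions are
#'   marked in the logical attribute `"flagged"`.
#' @export
z_score <- function(observed, null_stats) {
  x <- as.numeric(observed)
  mu <- as.numeric(null_stats$mean)
  sg <- as.numeric(null_stats$sd)
  stopifnot(length(x) == length(mu), length(mu) == length(sg))
  z <- numeric(length(x))
  flagged <- logical(length(x))
  ok <- sg > 0
  z[ok] <- (x[ok] - mu[ok]) / sg[ok]
  deg <- !ok & x != mu
  if (any(deg)) {
    fallback <- if (any(ok)) min(sg[ok]) else 1
    z[deg] <- (x[deg] - mu[deg]) / fallback
    flagged[deg] <- TRUE
  }
  names(z) <- names(.motif_map)
  attr(z, "flagged") <- flagged
  z
}

#' Normalise a z-score vector to unit length
#'
#' Divides by the Euclidean norm so that profiles of webs of different sizes
#' are comparable; larger networks otherwise show more extreme raw z-scores.
#' The zero vector maps to itself.
#'
#' @param z numeric vector of finite z-scores.
#' @return vector of the same length with unit Euclidean norm (or all zero).
#' @export
normalize_profile <- function(z) {
  zv <- as.numeric(z)
  if (any(!is.finite(zv)))
    stop("z-scores must be finite; see z_score() for the degenerate-sigma convention",
         call. = FALSE)
  nrm <- sqrt(sum(zv^2))
  out <- if (nrm > 0) zv / nrm else zv
  names(out) <- names(z)
  out
}

.profile_scope <- function(obs, mu, sd, iterations) {
  zs <- ns <- matrix(0, iterations, 13,
                     dimnames = list(NULL, names(.motif_map)))
  nflag <- 0L
  for (it in seq_len(iterations)) {
    z <- z_score(obs[it, ], list(mean = mu[it, ], sd = sd[it, ]))
    nflag <- nflag + sum(attr(z, "flagged"))
    zs[it, ] <- z
    ns[it, ] <- normalize_profile(z)
  }
  list(z_mean = colMeans(zs),
       n_mean = colMeans(ns),
       n_se = apply(ns, 2, sd) / sqrt(iterations),
       n_flagged = nflag)
}

#' Full motif profile of one plot-period
#'
#' For each sampling iteration of the probability matrix: draw a binary web,
#' census it, census an independent Curveball null ensemble, compute
#' z-scores, and normalise; then average the per-iteration normalised
#' profiles. The same sampled iteration is used for the full web and for its
#' consumer sub-web (free-floating motifs), each benchmarked against its own
#' ensemble.
#'
#' @param pweb a `prob_web`.
#' @param iterations sampled webs per probability matrix (default 50).
#' @param R null webs per sampled iteration (default 250).
#' @param trades_factor Curveball trades per null sample as a multiple of
#'   the number of consumer rows (default 5).
#' @param seed integer seed.
#' @return data frame with one row per class x scope: mean motif count,
#'   mean z, mean normalised score, its Monte-Carlo standard error, and the
#'   number of degenerate-sigma substitutions flagged.
#' @export
profile_pipeline <- function(pweb, iterations = 50, R = 250,
                             trades_factor = 5, seed = 1) {
  stopifnot(inherits(pweb, "prob_web"), iterations >= 1, R >= 2)
  set.seed(derive_seed(seed, pweb$plot_id, pweb$time_period, "profile"))
  idx <- which(pweb$A > 0, arr.ind = TRUE)
  ids <- pweb$nodes
  raw <- web_profile_cpp(idx[, 1] - 1L, idx[, 2] - 1L, pweb$A[idx],
                         length(ids),
                         pweb$roles[ids] %in% c("plant", "static_resource"),
                         iterations, R, trades_factor)
  sel <- match(.motif_map, .triad16)
  take <- function(m) {
    m <- m[, sel, drop = FALSE]
    colnames(m) <- names(.motif_map)
    m
  }
  res <- list(
    full = .profile_scope(take(raw$obs_full), take(raw$mu_full),
                          take(raw$sd_full), iterations),
    consumer_subweb = .profile_scope(take(raw$obs_sub), take(raw$mu_sub),
                                     take(raw$sd_sub), iterations))
  counts <- list(full = colMeans(take(raw$obs_full)),
                 consumer_subweb = colMeans(take(raw$obs_sub)))
  out <- do.call(rbind, lapply(names(res), function(scope) {
    data.frame(plot_id = pweb$plot_id, time_period = pweb$time_period,
               scope = scope, class = names(.motif_map),
               count_mean = unname(counts[[scope]]),
               z_mean = unname(res[[scope]]$z_mean),
               n_mean = unname(res[[scope]]$n_mean),
               n_se = unname(res[[scope]]$n_se),
               n_flagged = res[[scope]]$n_flagged,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
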