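# Cluster-based permutation testing on time x channel (ERP) and
# time x frequency x channel (TF) data, plus the behavioural one-sample t.
#
# Pointwise t maps are thresholded at a per-point alpha (two-tailed),
# suprathreshold points of common sign are joined into clusters under grid
# (time, frequency) adjacency plus a user-supplied channel neighbour
# relation, each cluster's mass is its summed t, and masses are referred to
# the permutation distribution of the per-permutation maximum mass
# (sign-flips of within-subject differences), separately per sign; with
# cluster significance at alpha/2 per side the family-wise error is alpha.

#' Channel adjacency specification
#'
#' @param pairs Two-column matrix or data frame of channel index pairs (or
#'   `NULL` for no channel neighbours, e.g. single-channel data). The
#'   relation is symmetrised.
#' @param n_channels Total number of channels.
#' @return Object of class `adjacency_spec`: a list of integer neighbour
#'   vectors, one per channel.
#' @export
adjacency_spec <- function(pairs = NULL, n_channels) {
  nb <- vector("list", n_channels)
  for (i in seq_len(n_channels)) nb[[i]] <- integer(0)
  if (!is.null(pairs) && NROW(pairs) > 0) {
    pairs <- as.matrix(pairs)
    storage.mode(pairs) <- "integer"
    if (any(pairs < 1 | pairs > n_channels))
      so_stop("parameter", "channel index out of range in adjacency pairs")
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      if (a == b) next
      nb[[a]] <- union(nb[[a]], b)
      nb[[b]] <- union(nb[[b]], a)
    }
  }
  structure(list(neighbors = nb, n_channels = n_channels),
            class = "adjacency_spec")
}

#' Read a channel neighbour file
#'
#' Tab-separated file with header `channel<TAB>neighbor`; channel names are
#' mapped to indices via `channel_names`.
#'
#' @param path File path.
#' @param channel_names Character vector fixing the channel order.
#' @return An [adjacency_spec()].
#' @export
read_neighbors <- function(path, channel_names) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character")
  a <- match(tab[[1]], channel_names)
  b <- match(tab[[2]], channel_names)
  if (anyNA(a) || anyNA(b))
    so_stop("parameter", "neighbor file mentions unknown channel names")
  adjacency_spec(cbind(a, b), length(channel_names))
}

#' Configuration for cluster permutation tests
#'
#' @param n_permutations Monte-Carlo iterations (default 1000), or `"all"`
#'   for exhaustive sign-flip enumeration (feasible for <= ~16 subjects).
#' @param cluster_alpha Per-point two-tailed threshold for cluster
#'   formation (default 0.01).
#' @param alpha_two_sided Cluster significance level per side (default
#'   0.025, i.e. 0.05 two-sided).
#' @param analysis_window_s Time window tested (default -0.2 to 1.5 s);
#'   points outside it are ignored.
#' @param seed Seed for the permutation draws (required for reproducible
#'   reports).
#' @return Object of class `cluster_config`.
#' @export
cluster_config <- function(n_permutations = 1000, cluster_alpha = 0.01,
                           alpha_two_sided = 0.025,
                           analysis_window_s = c(-0.200, 1.500),
                           seed = 1) {
  structure(list(n_permutations = n_permutations,
                 cluster_alpha = cluster_alpha,
                 alpha_two_sided = alpha_two_sided,
                 analysis_window_s = analysis_window_s,
                 seed = as.integer(seed)),
            class = "cluster_config")
}

## ---- internal machinery ----------------------------------------------------

## Maps: subjects x channels [x freqs] x time arrays. Internally flattened to
## subjects x P with P = channels * freqs * time and a point -> (ch, f, t)
## index so adjacency can be computed arithmetically.
flatten_maps <- function(maps, times_s, cfg) {
  d <- dim(maps)
  if (length(d) == 3) d <- c(d[1], d[2], 1L, d[3])
  x <- array(maps, d)
  tsel <- if (!is.null(times_s))
    which(times_s >= cfg$analysis_window_s[1] & times_s <= cfg$analysis_window_s[2])
  else seq_len(d[4])
  x <- x[, , , tsel, drop = FALSE]
  d <- dim(x)
  list(X = matrix(x, d[1], prod(d[-1])), n_ch = d[2], n_f = d[3],
       n_t = d[4], tsel = tsel, has_freq = length(dim(maps)) == 4)
}

## neighbours of flat point index p (1-based): grid +-1 in freq and time,
## channel neighbours at the same (freq, time). Flat layout: ch fastest,
## then freq, then time.
point_neighbors <- function(p, n_ch, n_f, n_t, chan_nb) {
  p0 <- p - 1L
  ch <- p0 %% n_ch
  f <- (p0 %/% n_ch) %% n_f
  t <- p0 %/% (n_ch * n_f)
  out <- integer(0)
  if (t > 0L) out <- c(out, p - n_ch * n_f)
  if (t < n_t - 1L) out <- c(out, p + n_ch * n_f)
  if (f > 0L) out <- c(out, p - n_ch)
  if (f < n_f - 1L) out <- c(out, p + n_ch)
  nb <- chan_nb[[ch + 1L]]
  if (length(nb)) out <- c(out, p + (nb - 1L - ch))
  out
}

## Connected components of the suprathreshold set; returns a list of
## integer vectors of flat indices. `mask` is logical over all P points.
find_clusters <- function(mask, n_ch, n_f, n_t, chan_nb) {
  idx <- which(mask)
  if (!length(idx)) return(list())
  in_set <- logical(length(mask))
  in_set[idx] <- TRUE
  seen <- logical(length(mask))
  out <- list()
  for (s in idx) {
    if (seen[s]) next
    comp <- integer(0)
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, p)
      nb <- point_neighbors(p, n_ch, n_f, n_t, chan_nb)
      nb <- nb[nb >= 1 & nb <= length(mask)]
      nb <- nb[in_set[nb] & !seen[nb]]
      if (length(nb)) {
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    out[[length(out) + 1L]] <- comp
  }
  out
}

## one-sample t statistics per column of X under sign vector s (vectorised
## over points; the column sum of squares is sign-invariant).
t_map_signed <- function(X, s) {
  n <- nrow(X)
  m <- as.numeric(s %*% X) / n
  ss <- .colSums(X^2, n, ncol(X))
  v <- (ss - n * m^2) / (n - 1)
  m / sqrt(pmax(v, .Machine$double.xmin) / n)
}

## per-permutation extreme cluster masses (max positive, min negative)
extreme_masses <- function(tv, thr, n_ch, n_f, n_t, chan_nb) {
  pos <- find_clusters(tv > thr, n_ch, n_f, n_t, chan_nb)
  neg <- find_clusters(tv < -thr, n_ch, n_f, n_t, chan_nb)
  c(max(c(0, vapply(pos, function(ii) sum(tv[ii]), 0))),
    min(c(0, vapply(neg, function(ii) sum(tv[ii]), 0))))
}

cluster_engine <- function(X, fl, adjacency, cfg) {
  n <- nrow(X)
  if (n < 2) so_stop("insufficient_data", "need at least two subjects")
  chan_nb <- if (is.null(adjacency)) vector("list", fl$n_ch) else adjacency$neighbors
  if (length(chan_nb) != fl$n_ch)
    so_stop("parameter", "adjacency channel count does not match the data")
  thr <- qt(1 - cfg$cluster_alpha / 2, df = n - 1)

  t_obs <- t_map_signed(X, rep(1, n))
  pos <- find_clusters(t_obs > thr, fl$n_ch, fl$n_f, fl$n_t, chan_nb)
  neg <- find_clusters(t_obs < -thr, fl$n_ch, fl$n_f, fl$n_t, chan_nb)
  clusters <- c(
    lapply(pos, function(ii) list(indices = ii, mass = sum(t_obs[ii]), sign = 1L)),
    lapply(neg, function(ii) list(indices = ii, mass = sum(t_obs[ii]), sign = -1L))
  )

  exhaustive <- identical(cfg$n_permutations, "all")
  if (exhaustive) {
    if (n > 16) so_stop("parameter", "exhaustive enumeration limited to n <= 16")
    B <- 2^n
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    B <- cfg$n_permutations
    set.seed(cfg$seed)
    signs <- matrix(sample(c(1, -1), B * n, replace = TRUE), B, n)
  }
  null_max <- matrix(0, NROW(signs), 2)
  for (b in seq_len(NROW(signs))) {
    tv <- t_map_signed(X, signs[b, ])
    null_max[b, ] <- extreme_masses(tv, thr, fl$n_ch, fl$n_f, fl$n_t, chan_nb)
  }

  for (i in seq_along(clusters)) {
    m <- clusters[[i]]$mass
    if (exhaustive) {
      p <- if (m > 0) mean(null_max[, 1] >= m) else mean(null_max[, 2] <= m)
    } else {
      p <- if (m > 0) (sum(null_max[, 1] >= m) + 1) / (B + 1)
           else (sum(null_max[, 2] <= m) + 1) / (B + 1)
    }
    clusters[[i]]$p_value <- p
    clusters[[i]]$significant <- p <= cfg$alpha_two_sided
    ## member coordinates (ch, freq, time) in the analysis window
    ii <- clusters[[i]]$indices - 1L
    clusters[[i]]$members <- data.frame(
      channel = ii %% fl$n_ch + 1L,
      freq = (ii %/% fl$n_ch) %% fl$n_f + 1L,
      time = ii %/% (fl$n_ch * fl$n_f) + 1L)
  }
  ord <- order(-abs(vapply(clusters, `[[`, 0, "mass")))
  structure(list(clusters = clusters[ord],
                 t_map = t_obs,
                 threshold = thr,
                 n_subjects = n,
                 n_permutations = if (exhaustive) B else cfg$n_permutations,
                 exhaustive = exhaustive,
                 cluster_alpha = cfg$cluster_alpha,
                 alpha_two_sided = cfg$alpha_two_sided,
                 dims = list(n_ch = fl$n_ch, n_f = fl$n_f, n_t = fl$n_t,
                             has_freq = fl$has_freq, tsel = fl$tsel)),
            class = "cluster_result")
}

## ---- public tests ----------------------------------------------------------

#' Paired cluster permutation test
#'
#' Tests condition A against condition B across subjects: per-point paired
#' t on the within-subject differences, cluster formation at
#' `cluster_alpha`, cluster mass against the permutation null obtained by
#' randomly swapping the two conditions within subjects (equivalently,
#' sign-flipping the differences).
#'
#' @param cond_a,cond_b Per-subject maps: subjects x channels x time
#'   arrays (ERP) or subjects x channels x freqs x time arrays (TF), equal
#'   shapes.
#' @param adjacency An [adjacency_spec()], or `NULL` for no channel
#'   neighbours.
#' @param cfg A [cluster_config()].
#' @param times_s Optional per-point latencies; when supplied, testing is
#'   restricted to `cfg$analysis_window_s`.
#' @return A `cluster_result`.
#' @export
paired_cluster_test <- function(cond_a, cond_b, adjacency = NULL,
                                cfg = cluster_config(), times_s = NULL) {
  if (!identical(dim(cond_a), dim(cond_b)))
    so_stop("parameter", "condition arrays must have identical shapes")
  one_sample_cluster_test(cond_a - cond_b, adjacency, cfg, times_s)
}

#' One-sample cluster permutation test against zero
#'
#' As [paired_cluster_test()], with per-point one-sample t against 0 and a
#' sign-flip permutation null.
#'
#' @param maps Per-subject maps (see [paired_cluster_test()]).
#' @inheritParams paired_cluster_test
#' @return A `cluster_result`.
#' @export
one_sample_cluster_test <- function(maps, adjacency = NULL,
                                    cfg = cluster_config(), times_s = NULL) {
  fl <- flatten_maps(maps, times_s, cfg)
  cluster_engine(fl$X, fl, adjacency, cfg)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d subject(s), %s permutations, point threshold |t| > %.2f\n",
              x$n_subjects,
              if (x$exhaustive) sprintf("exhaustive (%d)", x$n_permutations)
              else x$n_permutations, x$threshold))
  if (!length(x$clusters)) {
    cat("  no suprathreshold clusters\n")
    return(invisible(x))
  }
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  cluster %d: sign %+d, %d point(s), mass %.1f, p = %.4g%s\n",
                i, cl$sign, length(cl$indices), cl$mass, cl$p_value,
                if (cl$significant) " *" else ""))
  }
  invisible(x)
}

#' Channel-count heat map of a time-frequency cluster
#'
#' For each time-frequency point, the number of channels belonging to the
#' given cluster — the summary used to delineate windows of interest.
#'
#' @param result A `cluster_result` from time-frequency data.
#' @param cluster_index Which cluster to map (default 1, the largest).
#' @return Integer freqs x time matrix of channel counts.
#' @export
cluster_channel_heatmap <- function(result, cluster_index = 1) {
  stopifnot(inherits(result, "cluster_result"))
  if (!result$dims$has_freq)
    so_stop("shape", "heat map requires time-frequency (not ERP) clusters")
  d <- result$dims
  counts <- matrix(0L, d$n_f, d$n_t)
  if (cluster_index <= length(result$clusters)) {
    mem <- result$clusters[[cluster_index]]$members
    for (r in seq_len(nrow(mem)))
      counts[mem$freq[r], mem$time[r]] <- counts[mem$freq[r], mem$time[r]] + 1L
  }
  counts
}

#' One-sample t test
#'
#' Standard one-sample t against `mu` with `df = n - 1`. Zero variance with
#' a mean different from `mu` yields an infinite t, flagged via
#' `infinite = TRUE`.
#'
#' @param values Per-subject scalars (n >= 2).
#' @param mu Null value (e.g. 50 for two-alternative forced-choice
#'   percentage at chance).
#' @return List with `t`, `df`, `p`, `mean`, `sd`, `infinite`.
#' @export
one_sample_t <- function(values, mu = 0) {
  n <- length(values)
  if (n < 2) so_stop("insufficient_data", "one-sample t needs n >= 2")
  m <- mean(values); s <- sd(values)
  if (s == 0) {
    if (m == mu) return(list(t = 0, df = n - 1, p = 1, mean = m, sd = s,
                             infinite = FALSE))
    return(list(t = sign(m - mu) * Inf, df = n - 1, p = 0, mean = m, sd = s,
                infinite = TRUE))
  }
  tt <- (m - mu) / (s / sqrt(n))
  list(t = tt, df = n - 1, p = 2 * pt(-abs(tt), n - 1), mean = m, sd = s,
       infinite = FALSE)
}

#' One-sample t from summary statistics
#'
#' `t = (mean - mu) / (sd / sqrt(n))` — for checking published tables that
#' report only means and standard deviations.
#'
#' @param mean,sd,n Summary statistics.
#' @param mu Null value.
#' @return List with `t`, `df`, `p`.
#' @export
t_from_summary <- function(mean, sd, n, mu = 0) {
  tt <- (mean - mu) / (sd / sqrt(n))
  list(t = tt, df = n - 1, p = 2 * pt(-abs(tt), n - 1))
}
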