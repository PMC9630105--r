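#' Productivity time series
#'
#' A per-site net primary productivity (NPP) trajectory on a strictly ordered
#' time grid, with an explicit unit declaration. Units are never converted
#' silently: use [npp_convert()].
#'
#' @param site_id,region Identifiers.
#' @param times Time grid, kyr BP, strictly ordered (ascending or descending).
#' @param values NPP values, all >= 0, no missing values.
#' @param unit Declared unit string, `"g m-2 yr-1"` (canonical) or
#'   `"kg km-2 yr-1"`.
#' @return An `npp_series` object.
#' @export
npp_series <- function(site_id, region, times, values, unit = "g m-2 yr-1") {
  stopifnot(length(times) == length(values), length(times) >= 2)
  if (anyNA(values) || anyNA(times)) stop("missing values are not allowed")
  if (any(values < 0)) stop("NPP values must be non-negative")
  d <- diff(times)
  if (!(all(d > 0) || all(d < 0))) stop("time grid must be strictly ordered")
  structure(list(site_id = site_id, region = region, times = times,
                 values = values, unit = unit),
            class = "npp_series")
}

#' @export
print.npp_series <- function(x, ...) {
  cat(sprintf("NPP series %s (%s): %d points, %.3g-%.3g kyr BP, unit %s\n",
              x$site_id, x$region, length(x$times), min(x$times), max(x$times),
              x$unit))
  invisible(x)
}

#' Convert NPP between unit conventions
#'
#' 1 g m-2 yr-1 = 1000 kg km-2 yr-1.
#'
#' @param x Numeric values or an [npp_series].
#' @param from,to Unit strings (`from` taken from the series when `x` is one).
#' @export
npp_convert <- function(x, from = NULL, to = "g m-2 yr-1") {
  units <- c("g m-2 yr-1" = 1, "kg km-2 yr-1" = 1000)  # factors per g m-2
  if (inherits(x, "npp_series")) {
    from <- from %||% x$unit
    x$values <- npp_convert(x$values, from, to)
    x$unit <- to
    return(x)
  }
  if (is.null(from)) stop("source unit must be declared")
  if (!from %in% names(units) || !to %in% names(units))
    stop("unknown NPP unit; known: ", paste(names(units), collapse = ", "))
  x * units[[to]] / units[[from]]
}

#' First-difference temporal correlation of two series
#'
#' CORT measures whether two equal-length series move together: the
#' correlation-like ratio of the inner product of their first differences to
#' the product of the difference norms. 1 means the series rise and fall at
#' the same rate in every interval, -1 perfect anti-phase, 0 independent
#' trends.
#'
#' @param s1,s2 Numeric vectors of equal length >= 2, on aligned time grids,
#'   or [npp_series] objects.
#' @return Value in \[-1, 1\]; a constant series yields 0 with a warning.
#' @export
cort <- function(s1, s2) {
  u <- series_values(s1); v <- series_values(s2)
  check_aligned(s1, s2)
  stopifnot(length(u) == length(v), length(u) >= 2)
  du <- diff(u); dv <- diff(v)
  den <- sqrt(sum(du^2)) * sqrt(sum(dv^2))
  if (den == 0) {
    warning("degenerate (constant) series: temporal correlation undefined, returning 0")
    return(0)
  }
  sum(du * dv) / den
}

series_values <- function(s) if (inherits(s, "npp_series")) s$values else as.numeric(s)

check_aligned <- function(s1, s2) {
  if (inherits(s1, "npp_series") && inherits(s2, "npp_series")) {
    if (length(s1$times) != length(s2$times) ||
        any(abs(s1$times - s2$times) > 1e-9))
      stop("series are not aligned to a common time grid; resample explicitly first")
  }
  invisible(TRUE)
}

#' Adaptive tuning function
#'
#' f(x) = 2 / (1 + exp(k x)), k >= 0: the weight applied to the raw-value
#' distance according to the temporal correlation x. f(0) = 1 for every k;
#' for k > 0 it decreases strictly from 2 (perfect anti-phase) to 0 (perfect
#' co-movement). With the default k = 2, a perfectly co-moving pair keeps
#' only f(1) = 2/(1 + e^2) of its raw distance, i.e. the temporal-behaviour
#' term contributes (1 - f(1)) = 76% of the dissimilarity.
#'
#' @param x Temporal correlation value(s).
#' @param k Tuning constant, >= 0 (default 2).
#' @export
tuning <- function(x, k = 2) {
  if (k < 0) stop("tuning constant k must be >= 0")
  2 / (1 + exp(k * x))
}

#' Temporal-correlation-weighted dissimilarity
#'
#' dCORT combines proximity of raw values with similarity of temporal
#' behaviour: the Euclidean distance between the value vectors, modulated by
#' the tuning function of the first-difference correlation,
#' dCORT(S1, S2) = f(CORT(S1, S2)) * d(S1, S2).
#'
#' @inheritParams cort
#' @param k Tuning constant (default 2).
#' @return Non-negative dissimilarity; 0 iff the raw vectors are identical.
#' @export
dcort <- function(s1, s2, k = 2) {
  u <- series_values(s1); v <- series_values(s2)
  check_aligned(s1, s2)
  d <- sqrt(sum((u - v)^2))
  if (d == 0) return(0)
  tuning(cort(u, v), k) * d
}

#' Pairwise dCORT dissimilarity matrix
#'
#' @param series A list of [npp_series] (all on one time grid) or a numeric
#'   matrix with one series per row.
#' @param k Tuning constant.
#' @return A symmetric matrix with zero diagonal, row/column names taken from
#'   site ids or row names.
#' @export
dissimilarity_matrix <- function(series, k = 2) {
  if (is.matrix(series)) {
    ids <- rownames(series) %||% paste0("S", seq_len(nrow(series)))
    series <- stats::setNames(lapply(seq_len(nrow(series)),
                                     function(i) series[i, ]), ids)
  }
  n <- length(series)
  ids <- vapply(seq_len(n), function(i) {
    s <- series[[i]]
    if (inherits(s, "npp_series")) s$site_id
    else names(series)[i] %||% paste0("S", i)
  }, "")
  if (anyNA(ids) || any(!nzchar(ids))) ids <- paste0("S", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    D[i, j] <- D[j, i] <- suppressWarnings(dcort(series[[i]], series[[j]], k = k))
  }
  D
}

#' Cluster productivity trajectories
#'
#' Agglomerative hierarchical clustering (average linkage by default) of a
#' dissimilarity matrix, cut into a requested number of groups.
#' Deterministic given the matrix.
#'
#' @param D Square symmetric dissimilarity matrix (e.g. from
#'   [dissimilarity_matrix()]).
#' @param n_clusters Number of groups to cut (default 3).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return List with `labels` (named integer vector) and `tree` (an `hclust`).
#' @export
cluster_series <- function(D, n_clusters = 3, linkage = "average") {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (n_clusters > nrow(D))
    stop("n_clusters exceeds the number of series")
  tree <- stats::hclust(stats::as.dist(D), method = linkage)
  labels <- stats::cutree(tree, k = n_clusters)
  list(labels = labels, tree = tree)
}

#' Regional composition of clusters
#'
#' Cross-tabulates cluster labels against regions and row-normalises to
#' percentages (each region row sums to 100).
#'
#' @param labels Cluster assignment per series.
#' @param regions Region per series (same length).
#' @return Matrix of percentages, regions x clusters.
#' @export
cluster_region_composition <- function(labels, regions) {
  stopifnot(length(labels) == length(regions))
  tab <- table(region = regions, cluster = labels)
  100 * prop.table(tab, margin = 1)
}

#' Jaccard similarity of two species sets
#'
#' JSI = c / (a + b + c): shared species over total distinct species.
#'
#' @param a_set,b_set Character vectors of taxon names (non-empty).
#' @return Value in \[0, 1\]; symmetric.
#' @export
jsi <- function(a_set, b_set) {
  a_set <- unique(a_set); b_set <- unique(b_set)
  if (length(a_set) == 0 && length(b_set) == 0)
    stop("Jaccard similarity undefined for two empty sets")
  length(intersect(a_set, b_set)) / length(union(a_set, b_set))
}

#' Stadial/interstadial phase tables
#'
#' Builds and validates a table of named Greenland stadial (GS) and
#' interstadial (GI) phases. Phases must be non-overlapping, with start >
#' end in BP magnitude, and alternate in kind. `read_phase_table()` reads
#' the CSV schema `name, kind, start_kyr_bp, end_kyr_bp`.
#'
#' @param df Data frame with columns `name`, `kind` (`stadial` /
#'   `interstadial`), `start_kyr_bp`, `end_kyr_bp`.
#' @return A validated `phase_table` (data frame, oldest first).
#' @export
phase_table <- function(df) {
  stopifnot(all(c("name", "kind", "start_kyr_bp", "end_kyr_bp") %in% names(df)))
  if (!all(df$kind %in% c("stadial", "interstadial")))
    stop("phase kind must be 'stadial' or 'interstadial'")
  if (any(df$start_kyr_bp <= df$end_kyr_bp))
    stop("each phase must have start > end (kyr BP)")
  df <- df[order(-df$start_kyr_bp), , drop = FALSE]
  if (nrow(df) > 1) {
    if (any(df$end_kyr_bp[-nrow(df)] < df$start_kyr_bp[-1] - 1e-9))
      stop("phases overlap")
    if (any(df$kind[-1] == df$kind[-nrow(df)]))
      stop("phase kinds must alternate")
  }
  rownames(df) <- NULL
  structure(df, class = c("phase_table", "data.frame"))
}

#' @param path CSV path.
#' @rdname phase_table
#' @export
read_phase_table <- function(path) {
  phase_table(utils::read.csv(path, comment.char = "#",
                              stringsAsFactors = FALSE))
}

#' Convert ice-core b2k ages to BP
#'
#' Ice-core chronologies are reported relative to AD 2000 (b2k); radiocarbon
#' ages relative to AD 1950 (BP). Subtracts 0.05 kyr.
#'
#' @param kyr_b2k Ages in kyr b2k.
#' @export
b2k_to_bp <- function(kyr_b2k) kyr_b2k - 0.05

#' Classify time points into phases
#'
#' @param times_kyr Time points, kyr BP.
#' @param phases A [phase_table]. A point t belongs to the phase with
#'   start >= t > end.
#' @return Data frame with `phase` and `kind` per point (NA if unclassifiable).
#' @export
classify_phase <- function(times_kyr, phases) {
  nm <- rep(NA_character_, length(times_kyr))
  kd <- rep(NA_character_, length(times_kyr))
  for (i in seq_len(nrow(phases))) {
    inphase <- times_kyr <= phases$start_kyr_bp[i] & times_kyr > phases$end_kyr_bp[i]
    nm[inphase] <- phases$name[i]
    kd[inphase] <- phases$kind[i]
  }
  data.frame(phase = nm, kind = kd)
}

#' Phase-stratified productivity statistics
#'
#' Splits a productivity series into stadial and interstadial subsets and
#' reports mean, standard deviation and coefficient of variation
#' (CV% = 100 sd/mean) per kind, plus a two-sided Wilcoxon rank-sum test of
#' the stadial against the interstadial values.
#'
#' @param times Time points, kyr BP (or an [npp_series] as first argument).
#' @param values NPP values (ignored when `times` is an `npp_series`).
#' @param phases A [phase_table].
#' @return List with `summary` (data frame, one row per kind) and `test`
#'   (list `W`, `p`). Unclassifiable points are excluded with a warning.
#' @export
phase_stats <- function(times, values = NULL, phases) {
  if (inherits(times, "npp_series")) { values <- times$values; times <- times$times }
  cls <- classify_phase(times, phases)
  if (anyNA(cls$kind)) {
    warning(sum(is.na(cls$kind)), " time point(s) fall outside the phase table and were excluded: ",
            paste(utils::head(times[is.na(cls$kind)], 5), collapse = ", "))
    values <- values[!is.na(cls$kind)]
    cls <- cls[!is.na(cls$kind), , drop = FALSE]
  }
  kinds <- c("stadial", "interstadial")
  summ <- do.call(rbind, lapply(kinds, function(k) {
    v <- values[cls$kind == k]
    data.frame(kind = k, n = length(v), mean = mean(v), sd = stats::sd(v),
               cv_pct = if (mean(v) != 0) 100 * stats::sd(v) / mean(v) else 0)
  }))
  st <- values[cls$kind == "stadial"]
  it <- values[cls$kind == "interstadial"]
  if (length(st) < 2 || length(it) < 2)
    stop("at least 2 points per phase kind are required for the rank-sum test")
  if (diff(range(c(st, it))) == 0) {
    # all values tied: the two samples are indistinguishable by construction
    test <- list(W = length(st) * length(it) / 2, p = 1)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(st, it))
    test <- list(W = unname(wt$statistic), p = wt$p.value)
  }
  list(summary = summ, test = test)
}

#' Percent change in mean productivity between two phases
#'
#' 100 * (mean_to - mean_from) / mean_from: negative values are decreases.
#'
#' @inheritParams phase_stats
#' @param phase_from,phase_to Phase names present in the table.
#' @export
percent_change <- function(times, values = NULL, phases, phase_from, phase_to) {
  if (inherits(times, "npp_series")) { values <- times$values; times <- times$times }
  cls <- classify_phase(times, phases)
  m_from <- mean(values[cls$phase %in% phase_from])
  m_to <- mean(values[cls$phase %in% phase_to])
  if (!is.finite(m_from) || !is.finite(m_to))
    stop("both phases must contain data points")
  if (m_from == 0) stop("baseline phase mean is zero; percent change undefined")
  100 * (m_to - m_from) / m_from
}
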