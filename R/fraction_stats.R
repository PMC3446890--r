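#' Probe-by-fraction expression data
#'
#' The container for "fraction data": a probe x fraction matrix of
#' non-negative microarray intensities with companion present/absent flags.
#' Fraction columns are named by series label and slab index ("S1".."Ho7" in
#' the 61-fraction reference design).
#'
#' @param intensity Numeric probe x fraction matrix with row names (probe
#'   ids) and column names (fraction labels).
#' @param present Logical matrix of the same shape: microarray present-flag
#'   calls. Defaults to all `TRUE`.
#' @return An object of class `fraction_data` with fields `probes`,
#'   `fractions`, `intensity`, `present` and `fraction_info` (tibble:
#'   `fraction`, `series_id`, `index`).
#' @export
fraction_data <- function(intensity, present = NULL) {
  intensity <- as.matrix(intensity)
  if (is.null(colnames(intensity)) ||
      (nrow(intensity) > 0L && is.null(rownames(intensity)))) {
    stop("`intensity` needs probe row names and fraction column names", call. = FALSE)
  }
  if (is.null(rownames(intensity))) rownames(intensity) <- character(0)
  if (anyDuplicated(rownames(intensity))) stop("duplicate probe ids", call. = FALSE)
  if (anyDuplicated(colnames(intensity))) stop("duplicate fraction labels", call. = FALSE)
  storage.mode(intensity) <- "double"
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  if (is.null(present)) {
    present <- matrix(TRUE, nrow(intensity), ncol(intensity),
                      dimnames = dimnames(intensity))
  }
  present <- as.matrix(present)
  if (!identical(dim(present), dim(intensity)) || !is.logical(present)) {
    stop("`present` must be a logical matrix matching `intensity`", call. = FALSE)
  }
  dimnames(present) <- dimnames(intensity)
  fr <- colnames(intensity)
  m <- regmatches(fr, regexec("^([A-Za-z]+?)(o?)([0-9]+)$", fr))
  series_id <- vapply(m, function(x) if (length(x)) paste0(x[2], x[3]) else NA_character_,
                      character(1))
  index <- vapply(m, function(x) if (length(x)) as.integer(x[4]) else NA_integer_,
                  integer(1))
  structure(
    list(
      probes = rownames(intensity), fractions = fr,
      intensity = intensity, present = present,
      fraction_info = tibble::tibble(fraction = fr, series_id = series_id, index = index)
    ),
    class = "fraction_data"
  )
}

#' @export
print.fraction_data <- function(x, ...) {
  cat(sprintf("<fraction_data> %s probes x %d fractions (%.1f%% present flags)\n",
              format(length(x$probes), big.mark = ","), length(x$fractions),
              100 * mean(x$present)))
  invisible(x)
}

#' @export
dim.fraction_data <- function(x) dim(x$intensity)

#' Long-format view of fraction data
#' @param x A `fraction_data`.
#' @param ... Unused.
#' @return Tibble with columns `probe_id`, `fraction`, `series_id`, `index`,
#'   `intensity`, `present`.
#' @export
as_tibble.fraction_data <- function(x, ...) {
  long <- tibble::tibble(
    probe_id = rep(x$probes, times = length(x$fractions)),
    fraction = rep(x$fractions, each = length(x$probes)),
    intensity = as.numeric(x$intensity),
    present = as.logical(x$present)
  )
  dplyr::left_join(long, x$fraction_info, by = "fraction")
}

# log2 intensities with the stabilising +1 offset used throughout
log2_intensity <- function(fd) log2(fd$intensity + 1)

#' Per-chip intensity normalisation
#'
#' Scales every fraction (one microarray chip) to a common reference level:
#' each column is divided by its 75th-percentile intensity (the GeneSpring-
#' style per-chip target), or by its median with `target = "median"`.
#'
#' @param fd A `fraction_data`.
#' @param target `"p75"` (default) or `"median"`.
#' @return A `fraction_data` with normalised intensities (each column's
#'   target percentile equals 1 afterwards).
#' @export
normalize_per_chip <- function(fd, target = c("p75", "median")) {
  stopifnot(inherits(fd, "fraction_data"))
  target <- match.arg(target)
  p <- if (target == "p75") 0.75 else 0.5
  sc <- apply(fd$intensity, 2, quantile, probs = p, names = FALSE)
  if (any(sc <= 0)) {
    stop(sprintf("fraction(s) %s have a zero normalisation target",
                 paste(fd$fractions[sc <= 0], collapse = ", ")), call. = FALSE)
  }
  fraction_data(sweep(fd$intensity, 2, sc, "/"), fd$present)
}

#' Keep only "total probes" (at least one present flag)
#'
#' @param fd A `fraction_data`.
#' @return A `fraction_data` restricted to probes flagged present in at
#'   least one fraction (possibly zero rows).
#' @export
filter_total_probes <- function(fd) {
  stopifnot(inherits(fd, "fraction_data"))
  keep <- rowSums(fd$present) > 0L
  fraction_data(fd$intensity[keep, , drop = FALSE], fd$present[keep, , drop = FALSE])
}

#' Drop fractions with no signal in any probe
#'
#' Removes all-zero fraction columns (slabs that contain no tissue in a
#' design whose span overhangs the mask), which would otherwise make
#' correlations undefined.
#'
#' @param fd A `fraction_data`.
#' @return A `fraction_data` without the all-zero fractions.
#' @export
drop_empty_fractions <- function(fd) {
  stopifnot(inherits(fd, "fraction_data"))
  keep <- colSums(fd$intensity) > 0
  fraction_data(fd$intensity[, keep, drop = FALSE], fd$present[, keep, drop = FALSE])
}

#' Pairwise inter-fraction correlations
#'
#' Pearson correlation between every pair of fractions over log2(intensity
#' + 1) across probes, summarised over the strictly-upper triangle
#' (mean with standard error, minimum, maximum).
#'
#' @param fd A `fraction_data` with at least 2 probes and 2 fractions.
#' @return A list of class `fraction_cor`: `r` (fraction x fraction matrix)
#'   and `summary` (one-row tibble: `mean_r`, `sem_r`, `min_r`, `max_r`,
#'   `n_pairs`).
#' @export
fraction_correlations <- function(fd) {
  stopifnot(inherits(fd, "fraction_data"))
  if (length(fd$probes) < 2L || length(fd$fractions) < 2L) {
    stop("need at least 2 probes and 2 fractions", call. = FALSE)
  }
  lx <- log2_intensity(fd)
  sds <- apply(lx, 2, sd)
  if (any(sds == 0)) {
    stop(sprintf("fraction(s) %s are constant across probes; r is undefined",
                 paste(fd$fractions[sds == 0], collapse = ", ")), call. = FALSE)
  }
  r <- cor(lx)
  up <- r[upper.tri(r)]
  structure(
    list(
      r = r,
      summary = tibble::tibble(
        mean_r = mean(up), sem_r = sd(up) / sqrt(length(up)),
        min_r = min(up), max_r = max(up), n_pairs = length(up)
      )
    ),
    class = "fraction_cor"
  )
}

#' @export
print.fraction_cor <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<fraction_cor> mean r %.3f +/- %.2g (sem), range [%.3f, %.3f], %d pairs\n",
              s$mean_r, s$sem_r, s$min_r, s$max_r, s$n_pairs))
  invisible(x)
}

#' Upper-triangle correlations as a tibble
#' @param x A `fraction_cor`.
#' @param ... Unused.
#' @return Tibble with columns `fraction_a`, `fraction_b`, `r`.
#' @export
tidy.fraction_cor <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    fraction_a = rownames(x$r)[idx[, 1]],
    fraction_b = colnames(x$r)[idx[, 2]],
    r = x$r[idx]
  )
}

#' @export
glance.fraction_cor <- function(x, ...) x$summary

#' Pair fractions across two groups as replicates
#'
#' The two sectioning groups (orthogonal S/C/H and oblique So/Co/Ho) sample
#' overlapping tissue, so anatomically matching fractions behave as
#' "slightly different" biological replicates. Pairs are chosen greedily by
#' descending Pearson correlation of log2 intensities; exact ties are broken
#' by anatomical order — a pair from the same body axis (S with So, etc.)
#' with the closest slab indices is preferred.
#'
#' @param fd A `fraction_data`.
#' @param group_a,group_b Character vectors of fraction labels; default to
#'   the orthogonal (S/C/H) and oblique (So/Co/Ho) fractions found in `fd`.
#'   Must be disjoint.
#' @return An object of class `replicate_pairing`: tibble `pairs`
#'   (`fraction_a`, `fraction_b`, `r`) plus `unpaired` labels.
#' @export
pair_replicates <- function(fd, group_a = NULL, group_b = NULL) {
  stopifnot(inherits(fd, "fraction_data"))
  info <- fd$fraction_info
  if (is.null(group_a)) group_a <- info$fraction[info$series_id %in% c("S", "C", "H")]
  if (is.null(group_b)) group_b <- info$fraction[info$series_id %in% c("So", "Co", "Ho")]
  group_a <- intersect(group_a, fd$fractions)
  group_b <- intersect(group_b, fd$fractions)
  if (length(intersect(group_a, group_b))) {
    stop("replicate groups overlap", call. = FALSE)
  }
  if (!length(group_a) || !length(group_b)) {
    stop("both replicate groups must be non-empty", call. = FALSE)
  }
  lx <- log2_intensity(fd)
  # constant columns (e.g. fractions with no tissue) have undefined r and
  # can never win a pairing: rank them below every defined correlation
  r <- suppressWarnings(cor(lx[, group_a, drop = FALSE], lx[, group_b, drop = FALSE]))
  r[is.na(r)] <- -Inf
  ia <- info$index[match(group_a, info$fraction)]
  ib <- info$index[match(group_b, info$fraction)]
  sa <- info$series_id[match(group_a, info$fraction)]
  sb <- info$series_id[match(group_b, info$fraction)]
  cand <- expand.grid(a = seq_along(group_a), b = seq_along(group_b))
  cand$r <- r[cbind(cand$a, cand$b)]
  cand$same_axis <- sa[cand$a] == sub("o$", "", sb[cand$b])
  cand$idx_dist <- abs(ia[cand$a] - ib[cand$b])
  # greedy sweep in descending r; anatomical order breaks exact ties
  ord <- order(-cand$r, !cand$same_axis, cand$idx_dist, ia[cand$a], ib[cand$b])
  cand <- cand[ord, ]
  free_a <- rep(TRUE, length(group_a))
  free_b <- rep(TRUE, length(group_b))
  pa <- integer(0); pb <- integer(0); pr <- numeric(0)
  for (k in seq_len(nrow(cand))) {
    if (!is.finite(cand$r[k])) next
    a <- cand$a[k]; b <- cand$b[k]
    if (free_a[a] && free_b[b]) {
      free_a[a] <- FALSE; free_b[b] <- FALSE
      pa <- c(pa, a); pb <- c(pb, b); pr <- c(pr, cand$r[k])
    }
  }
  structure(
    list(
      pairs = tibble::tibble(
        fraction_a = group_a[pa], fraction_b = group_b[pb], r = pr
      ),
      unpaired = c(group_a[free_a], group_b[free_b])
    ),
    class = "replicate_pairing"
  )
}

#' @export
print.replicate_pairing <- function(x, ...) {
  cat(sprintf("<replicate_pairing> %d pairs (mean r %.3f), %d unpaired fractions\n",
              nrow(x$pairs), mean(x$pairs$r), length(x$unpaired)))
  invisible(x)
}

#' @export
tidy.replicate_pairing <- function(x, ...) x$pairs

# vectorised one-way ANOVA across probes: each replicate pair is one level
# with 2 observations. Returns two-sided F-test p-values (NA-free; probes
# with zero within+between variance get p = 1).
row_anova_pairs <- function(lx, pairs) {
  k <- nrow(pairs)
  xa <- lx[, pairs$fraction_a, drop = FALSE]
  xb <- lx[, pairs$fraction_b, drop = FALSE]
  m <- (xa + xb) / 2                      # level means
  grand <- rowMeans(cbind(xa, xb))
  ssw <- rowSums((xa - m)^2 + (xb - m)^2) # df = 2k - k = k
  ssb <- 2 * rowSums((m - grand)^2)       # df = k - 1
  f <- (ssb / (k - 1)) / (ssw / k)
  p <- pf(f, k - 1, k, lower.tail = FALSE)
  p[ssb + ssw == 0] <- 1                  # constant probes: no variance at all
  p[ssw == 0 & ssb > 0] <- 0              # degenerate: all variance between levels
  p
}

#' Per-probe I/V variables and expression-uniformity classification
#'
#' Computes, for every probe on log2(intensity + 1) values: `I`, the median
#' intensity across all fractions; and `V`, the Benjamini-Hochberg-adjusted
#' false-discovery rate from a one-way ANOVA of expression variance across
#' fractions, with each replicate pair as one level (two observations per
#' level; unpaired fractions are excluded from the ANOVA). Probes are then
#' classified: letter I/i by whether `I` exceeds the median of all probes'
#' `I` (ties to i), and letter V/v by `V < fdr` (significant non-uniform
#' expression) — giving the four groups IV, iV, Iv, iv.
#'
#' @param fd A `fraction_data` (normalised intensities).
#' @param pairing A `replicate_pairing` with at least 2 pairs; defaults to
#'   [pair_replicates()] on the data's own groups.
#' @param fdr Significance level on the adjusted FDR (default 0.05).
#' @return An object of class `probe_stats`: tibble with columns `probe_id`,
#'   `I`, `p`, `V`, `group`, carrying attributes `group_counts` (named
#'   integer vector) and `i_v_cor` (Pearson r between `I` and `log10(V)`,
#'   a diagnostic of the two variables' independence).
#' @export
compute_iv <- function(fd, pairing = NULL, fdr = 0.05) {
  stopifnot(inherits(fd, "fraction_data"))
  if (is.null(pairing)) pairing <- pair_replicates(fd)
  stopifnot(inherits(pairing, "replicate_pairing"))
  if (nrow(pairing$pairs) < 2L) stop("need at least 2 replicate pairs", call. = FALSE)
  lx <- log2_intensity(fd)
  I <- unname(apply(lx, 1, median))
  p <- unname(row_anova_pairs(lx, pairing$pairs))
  V <- p.adjust(p, method = "BH")
  i_letter <- ifelse(I > median(I), "I", "i")
  v_letter <- ifelse(V < fdr, "V", "v")
  group <- paste0(i_letter, v_letter)
  out <- tibble::tibble(probe_id = fd$probes, I = I, p = p, V = V, group = group)
  counts <- table(factor(group, levels = c("IV", "iV", "Iv", "iv")))
  attr(out, "group_counts") <- stats::setNames(as.integer(counts), names(counts))
  attr(out, "i_v_cor") <- if (sd(I) > 0 && sd(log10(pmax(V, 1e-300))) > 0) {
    cor(I, log10(pmax(V, 1e-300)))
  } else NA_real_
  class(out) <- c("probe_stats", class(out))
  out
}

#' @export
print.probe_stats <- function(x, ...) {
  gc <- attr(x, "group_counts")
  cat(sprintf("<probe_stats> %s probes: IV %d, iV %d, Iv %d, iv %d\n",
              format(nrow(x), big.mark = ","), gc["IV"], gc["iV"], gc["Iv"], gc["iv"]))
  NextMethod()
}

#' Probe-group counts and I/V diagnostics
#' @param x A `probe_stats` table.
#' @param ... Unused.
#' @return One-row tibble: group counts, number significant, `i_v_cor`.
#' @export
glance.probe_stats <- function(x, ...) {
  gc <- attr(x, "group_counts")
  tibble::tibble(
    n_probes = nrow(x),
    n_IV = gc[["IV"]], n_iV = gc[["iV"]], n_Iv = gc[["Iv"]], n_iv = gc[["iv"]],
    n_significant = sum(x$V < 0.05),
    i_v_cor = attr(x, "i_v_cor")
  )
}

#' I-versus-V scatter of the probe classification
#' @param object A `probe_stats` table.
#' @param ... Unused.
#' @return A ggplot of `I` against `-log10(V)` coloured by group.
#' @export
autoplot.probe_stats <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$I, y = -log10(pmax(.data$V, 1e-300)),
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::labs(x = "I (median log2 intensity)", y = "-log10 V (BH FDR)",
                  colour = "group") +
    ggplot2::theme_minimal()
}
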