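#' Deterministic Hadamard-type matrices
#'
#' Constructs a Hadamard matrix of order `m` when one is reachable by
#' Sylvester doubling from the base orders 1, 2, 12 and 20 (the latter two
#' via the Paley construction on q = 11 and q = 19). Used to build balanced
#' pairwise-orthogonal subject splits. Returns `NULL` when the order is not
#' covered.
#'
#' @param m requested order.
#' @return An `m x m` matrix with entries +/-1 and `H %*% t(H) = m I`, or
#'   `NULL`.
#' @keywords internal
hadamard_matrix <- function(m) {
  if (m < 1) return(NULL)
  if (m == 1) return(matrix(1, 1, 1))
  base <- NULL
  r <- m
  while (r %% 2 == 0) r <- r / 2
  if (r == 1) base <- matrix(1, 1, 1)
  else if (r == 3 && m %% 12 == 0) base <- paley_hadamard(11)
  else if (r == 5 && m %% 20 == 0) base <- paley_hadamard(19)
  else return(NULL)
  h <- base
  while (nrow(h) < m)
    h <- rbind(cbind(h, h), cbind(h, -h))
  if (nrow(h) != m) return(NULL)
  h
}

paley_hadamard <- function(q) {
  stopifnot(q %% 4 == 3)
  qr <- unique((seq_len(q - 1)^2) %% q)
  chi <- function(a) {
    a <- a %% q
    ifelse(a == 0, 0, ifelse(a %in% qr, 1, -1))
  }
  jac <- outer(0:(q - 1), 0:(q - 1), function(i, j) chi(i - j))
  conf <- rbind(c(0, rep(1, q)), cbind(rep(-1, q), jac))
  conf + diag(q + 1)
}

#' Balanced pairwise-orthogonal subject splits
#'
#' Produces `k` divisions of `n` subjects into two equal groups such that
#' any two divisions agree on exactly `n/2` subjects (orthogonal splits, as
#' used to obtain independent group comparisons from one subject pool).
#' The construction takes `k` non-constant columns of a Hadamard matrix
#' whose order divides `n`, repeats each row `n/m` times, and applies a
#' seeded subject permutation; when no suitable Hadamard order exists a
#' seeded randomized search is attempted. Deterministic given `seed`.
#'
#' @param n number of subjects (even).
#' @param k number of splits.
#' @param seed integer seed.
#' @return An object of class `split_plan`: `assignments` is a `k x n`
#'   0/1 matrix (group membership per split).
#' @examples
#' sp <- orthogonal_splits(120, 6, seed = 1)
#' rowSums(sp$assignments)  # all 60
#' @export
orthogonal_splits <- function(n, k, seed = 1) {
  if (n %% 2 != 0 || n < 2) stop("'n' must be even and >= 2")
  if (k < 1) stop("'k' must be >= 1")
  if (k >= 2 && n %% 4 != 0)
    stop("k >= 2 balanced orthogonal splits require n divisible by 4 ",
         "(got n = ", n, "): two balanced splits of n subjects can only ",
         "agree on exactly n/2 of them when n/2 is even")
  assign01 <- NULL
  divisors <- which(n %% seq_len(n) == 0)
  for (m in divisors) {
    if (m < k + 1) next
    h <- hadamard_matrix(m)
    if (is.null(h)) next
    h <- h * rep(sign(h[, 1]), times = ncol(h))   # normalize col 1 to +1
    cols <- h[, 2:(k + 1), drop = FALSE]
    big <- cols[rep(seq_len(m), each = n / m), , drop = FALSE]
    assign01 <- t((big + 1) / 2)
    break
  }
  if (is.null(assign01))
    assign01 <- random_orthogonal_splits(n, k, seed)
  set.seed(seed)
  perm <- sample.int(n)
  assign01 <- assign01[, perm, drop = FALSE]
  storage.mode(assign01) <- "integer"
  structure(list(assignments = assign01, n = n, k = k, seed = seed),
            class = "split_plan")
}

random_orthogonal_splits <- function(n, k, seed, max_tries = 5000L) {
  set.seed(seed)
  acc <- matrix(numeric(0), nrow = 0, ncol = n)
  tries <- 0L
  while (nrow(acc) < k) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not construct ", k, " orthogonal balanced splits of ",
           n, " subjects (no suitable Hadamard order divides n and ",
           "randomized search failed)")
    cand <- rep(c(1, -1), each = n / 2)[sample.int(n)]
    if (nrow(acc) == 0 || all(abs(acc %*% cand) < 1e-9))
      acc <- rbind(acc, cand)
  }
  (acc + 1) / 2
}

#' Voxelwise two-sample t-map
#'
#' Pooled-variance two-sample t-statistic per voxel between two groups of
#' registered volumes; `df = nA + nB - 2`. Voxels with zero pooled
#' variance are `NA`.
#'
#' @param group_a,group_b lists of [volume_grid]s (>= 2 each, one grid).
#' @return List with `t` (a [volume_grid]) and `df`.
#' @export
two_sample_t_map <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("need at least 2 subjects per group")
  stop_if_geometry_differs(c(group_a, group_b), "subject volumes")
  ref <- group_a[[1]]
  na <- length(group_a); nb <- length(group_b)
  nvox <- length(ref$data)
  a <- matrix(vapply(group_a, function(v) as.numeric(v$data),
                     numeric(nvox)), nvox, na)
  b <- matrix(vapply(group_b, function(v) as.numeric(v$data),
                     numeric(nvox)), nvox, nb)
  ma <- rowMeans(a); mb <- rowMeans(b)
  ssa <- rowSums((a - ma)^2)
  ssb <- rowSums((b - mb)^2)
  df <- na + nb - 2L
  sp2 <- (ssa + ssb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- ifelse(se > 0, (ma - mb) / se, NA_real_)
  list(t = volume_grid(array(t, dim(ref$data)), affine = ref$affine,
                       voxel_size = ref$voxel_size),
       df = df)
}

#' Extract cluster peaks from a thresholded t-map
#'
#' Thresholds the map two-tailed at `p_threshold`, labels suprathreshold
#' voxels into 26-connected clusters, drops clusters smaller than
#' `min_extent`, and emits one peak per surviving cluster at its largest
#' `|t|` (sign preserved, first voxel in array order on ties), with the
#' coordinate reported in world mm.
#'
#' @param t_map [volume_grid] of t-statistics (`NA` ignored).
#' @param df degrees of freedom.
#' @param p_threshold two-tailed significance threshold.
#' @param min_extent minimum cluster size in voxels.
#' @return List of [peak] objects (`stat = "t"`), possibly empty; each
#'   carries a `cluster_size` attribute.
#' @export
extract_peaks <- function(t_map, df, p_threshold = 0.001, min_extent = 10) {
  if (!is.finite(df) || df < 1) stop("invalid degrees of freedom: ", df)
  tcrit <- stats::qt(1 - p_threshold / 2, df)
  tdat <- t_map$data
  supra <- which(!is.na(tdat) & abs(tdat) > tcrit)
  if (!length(supra)) return(list())
  d <- dim(tdat)
  no <- neighbor_offsets()$offsets
  labels <- integer(length(tdat))
  labels[supra] <- -1L  # unvisited suprathreshold
  clusters <- list()
  for (start in supra) {
    if (labels[start] != -1L) next
    lab <- length(clusters) + 1L
    queue <- start
    labels[start] <- lab
    members <- integer(0)
    while (length(queue)) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      members <- c(members, v)
      v0 <- v - 1L
      vi <- v0 %% d[1] + 1L
      vj <- (v0 %/% d[1]) %% d[2] + 1L
      vk <- v0 %/% (d[1] * d[2]) + 1L
      for (j in seq_len(nrow(no))) {
        ni <- vi + no[j, 1]; nj <- vj + no[j, 2]; nk <- vk + no[j, 3]
        if (ni < 1L || ni > d[1] || nj < 1L || nj > d[2] ||
            nk < 1L || nk > d[3]) next
        w <- (nk - 1L) * d[1] * d[2] + (nj - 1L) * d[1] + ni
        if (labels[w] == -1L) {
          labels[w] <- lab
          queue <- c(queue, w)
        }
      }
    }
    clusters[[lab]] <- members
  }
  out <- list()
  for (members in clusters) {
    if (length(members) < min_extent) next
    best <- members[which.max(abs(tdat[members]))]
    b0 <- best - 1L
    ijk0 <- c(b0 %% d[1], (b0 %/% d[1]) %% d[2], b0 %/% (d[1] * d[2]))
    pk <- peak(voxel_to_world(t_map, ijk0), tdat[best], stat = "t")
    attr(pk, "cluster_size") <- length(members)
    out[[length(out) + 1L]] <- pk
  }
  out
}

#' Relative mean squared recreation error
#'
#' `100 * mean((recreated - truth)^2 over the mask) / reference_mse`, the
#' recreation score: values below 100% improve on the reference setting
#' (isotropic kernel, FWHM = 20 mm); the reference setting evaluated
#' against itself gives exactly 100%.
#'
#' @param recreated,truth [volume_grid]s or arrays on one grid.
#' @param mask logical array selecting scored voxels (non-empty).
#' @param reference_mse MSE of the reference setting (> 0).
#' @return Relative MSE in percent.
#' @export
relative_mse <- function(recreated, truth, mask, reference_mse) {
  if (!is.numeric(reference_mse) || reference_mse <= 0)
    stop("'reference_mse' must be positive")
  r <- if (is_volume_grid(recreated)) recreated$data else recreated
  t_ <- if (is_volume_grid(truth)) truth$data else truth
  if (!any(mask)) stop("empty mask")
  100 * mean((r[mask] - t_[mask])^2) / reference_mse
}

#' Wilcoxon signed-rank test (exact for small samples)
#'
#' Paired signed-rank test of `values` against `reference_values`. Zero
#' differences are dropped; with at most `exact_max` remaining pairs the
#' exact two-sided p-value is computed from the sign-flip distribution of
#' the rank sum (a small dynamic program over midranks, valid with tied
#' absolute differences and identical to the classical signed-rank
#' distribution without ties), otherwise a normal approximation with tie
#' correction and continuity correction is used. All-zero differences give
#' p = 1 with a warning. Deterministic.
#'
#' @param values,reference_values paired numeric vectors.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @param exact_max largest n for which the exact distribution is used.
#' @return List with `p`, `statistic` (W+ = sum of positive ranks), `n`
#'   (pairs after zero removal), `method`.
#' @export
wilcoxon_signed_rank <- function(values, reference_values,
                                 method = c("auto", "exact", "normal"),
                                 exact_max = 25L) {
  method <- match.arg(method)
  if (length(values) != length(reference_values) || !length(values))
    stop("'values' and 'reference_values' must be paired, non-empty")
  d <- values - reference_values
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; p = 1")
    return(list(p = 1, statistic = 0, n = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  use_exact <- method == "exact" || (method == "auto" && n <= exact_max)
  if (use_exact) {
    # distribution of 2*W under independent sign flips: generating-function
    # convolution over the doubled (integer) midranks
    r2 <- as.integer(round(2 * r))
    counts <- c(1, numeric(sum(r2)))
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    total <- 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(counts[seq_len(w2 + 1L)]) / total
    p_ge <- sum(counts[(w2 + 1L):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(p = p, statistic = w, n = n, method = "exact"))
  }
  mu <- n * (n + 1) / 4
  tab <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
  p <- 2 * stats::pnorm(-abs(z))
  list(p = min(1, p), statistic = w, n = n, method = "normal")
}

#' Score recreation accuracy over an (anisotropy, FWHM) grid
#'
#' Reproduces the empirical validation design: for each subject split, a
#' two-sample t-map is computed, thresholded (two-tailed `p_threshold`,
#' `min_extent`), cluster peaks are extracted and, per combination of
#' `alpha` and FWHM, an effect-size map is recreated from the peaks alone
#' and scored against the "true" effect-size map (the unthresholded t-map
#' converted voxelwise to `d`) by MSE over the tissue mask. Scores are
#' expressed relative to the reference setting (`alpha = 0`, FWHM = 20 mm)
#' of the same split, in percent, and each cell is compared with the
#' reference across splits by the signed-rank test.
#'
#' @param subject_volumes list of [volume_grid]s.
#' @param template [correlation_template] on the same grid.
#' @param alphas,fwhms evaluated parameter values.
#' @param split_plan a [orthogonal_splits] plan over the subjects.
#' @param p_threshold,min_extent peak-extraction settings.
#' @param mask_threshold tissue-probability level of the scoring mask.
#' @param reference reference setting, `c(alpha, fwhm)`.
#' @return An object of class `validation_grid`: `rel_mse`
#'   (alpha x fwhm x split, percent), `mse`, `reference_mse` (per split),
#'   `p_values` (alpha x fwhm), `n_peaks` (per split), plus the evaluated
#'   `alphas`, `fwhms` and `reference`.
#' @export
evaluate_grid <- function(subject_volumes, template, alphas, fwhms,
                          split_plan, p_threshold = 0.001, min_extent = 10,
                          mask_threshold = 0.1,
                          reference = c(alpha = 0, fwhm = 20)) {
  stopifnot(inherits(split_plan, "split_plan"),
            inherits(template, "correlation_template"))
  n <- length(subject_volumes)
  if (split_plan$n != n)
    stop("split plan is for ", split_plan$n, " subjects, got ", n)
  if (!same_geometry(subject_volumes[[1]], template$tissue_prob))
    stop("template geometry does not match the subject volumes")
  na_ <- length(alphas); nf <- length(fwhms); k <- split_plan$k
  mse <- array(NA_real_, c(na_, nf, k),
               dimnames = list(alpha = alphas, fwhm = fwhms, split = 1:k))
  ref_mse <- numeric(k)
  n_peaks <- integer(k)

  for (s in seq_len(k)) {
    g <- split_plan$assignments[s, ]
    ga <- subject_volumes[g == 0L]
    gb <- subject_volumes[g == 1L]
    tm <- two_sample_t_map(ga, gb)
    truth <- t_to_d(tm$t$data, length(ga), length(gb))
    mask <- template$tissue_prob$data >= mask_threshold & !is.na(truth)
    if (!any(mask)) stop("split ", s, ": empty scoring mask")
    pks <- extract_peaks(tm$t, tm$df, p_threshold, min_extent)
    n_peaks[s] <- length(pks)
    d_pks <- lapply(pks, function(pk)
      peak(pk$coord_mm, t_to_d(pk$value, length(ga), length(gb)), "d"))

    recreate_cell <- function(alpha, fwhm) {
      cfg <- kernel_config(fwhm_mm = fwhm, alpha = alpha,
                           tissue_threshold = mask_threshold)
      if (!length(d_pks))
        return(array(0, dim(truth)))
      maps <- list(); wts <- list()
      for (pk in d_pks) {
        rec <- recreate_from_peak(template, pk, cfg, return_weight = TRUE)
        maps[[length(maps) + 1L]] <- rec$value
        wts[[length(wts) + 1L]] <- rec$weight
      }
      combine_peak_maps(maps, wts)$data
    }

    ref_rec <- recreate_cell(reference[["alpha"]], reference[["fwhm"]])
    ref_mse[s] <- mean((ref_rec[mask] - truth[mask])^2)
    if (ref_mse[s] <= 0)
      stop("split ", s, ": reference MSE is zero; cannot form relative MSE")
    for (ai in seq_len(na_)) for (fi in seq_len(nf)) {
      if (alphas[ai] == reference[["alpha"]] &&
          fwhms[fi] == reference[["fwhm"]]) {
        mse[ai, fi, s] <- ref_mse[s]
        next
      }
      rec <- recreate_cell(alphas[ai], fwhms[fi])
      mse[ai, fi, s] <- mean((rec[mask] - truth[mask])^2)
    }
  }

  rel <- sweep(mse, 3, ref_mse, "/") * 100
  p_values <- matrix(NA_real_, na_, nf,
                     dimnames = list(alpha = alphas, fwhm = fwhms))
  for (ai in seq_len(na_)) for (fi in seq_len(nf)) {
    p_values[ai, fi] <- suppressWarnings(
      wilcoxon_signed_rank(mse[ai, fi, ], ref_mse)$p)
  }
  structure(list(alphas = alphas, fwhms = fwhms, rel_mse = rel, mse = mse,
                 reference_mse = ref_mse, p_values = p_values,
                 n_peaks = n_peaks, reference = reference),
            class = "validation_grid")
}

#' @export
print.validation_grid <- function(x, ...) {
  cat("<validation_grid> relative MSE (%), mean over",
      dim(x$rel_mse)[3], "splits\n")
  print(round(apply(x$rel_mse, c(1, 2), mean), 1))
  cat("peaks per split:", paste(x$n_peaks, collapse = ", "), "\n")
  invisible(x)
}
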