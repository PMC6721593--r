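# Independent oracles used to check the implementation on small fixtures.

# brute-force maximizer of the Cox log partial likelihood for one covariate,
# tie-free fixtures only (Efron = Breslow = exact without ties)
cox_pl_oracle <- function(time, event, x, grid = seq(-5, 5, by = 1e-4)) {
  stopifnot(!anyDuplicated(time[event == 1]))
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  logpl <- vapply(grid, function(beta) {
    ex <- exp(beta * x)
    # risk set of subject i: all j with time_j >= time_i
    denom <- rev(cumsum(rev(ex)))
    sum((beta * x - log(denom))[event == 1])
  }, numeric(1))
  grid[which.max(logpl)]
}

# exhaustive Youden scan over midpoint thresholds, naive double loop
youden_scan_oracle <- function(scores, event) {
  event <- as.logical(event)
  u <- sort(unique(scores))
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- NULL
  for (th in cand) {
    sens <- sum(scores[event] >= th) / sum(event)
    spec <- sum(scores[!event] < th) / sum(!event)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) best <- list(th = th, j = j)
  }
  best
}

# two-sided Fisher exact p by hypergeometric enumeration over all 2x2 tables
# with the observed margins
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-group log-rank chi-square from first principles
logrank_oracle <- function(time, event, group) {
  group <- as.factor(group)
  g1 <- levels(group)[1]
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# naive voxel dilation: center within margin of some mask voxel center
naive_dilate <- function(vol, mask, margin_mm) {
  dims <- dim(vol$values)
  all_idx <- as.matrix(expand.grid(i = 1:dims[1], j = 1:dims[2],
                                   k = 1:dims[3]))
  centers <- sweep(sweep(all_idx - 1, 2, vol$spacing_mm, "*"), 2,
                   vol$origin_mm, "+")
  src <- centers[which(mask), , drop = FALSE]
  hit <- apply(centers, 1, function(p)
    min(colSums((t(src) - p)^2)) <= margin_mm^2 + 1e-9)
  out <- array(FALSE, dims)
  out[all_idx[hit, , drop = FALSE]] <- TRUE
  out
}

# small isotropic phantom for fast imaging tests
small_phantom_spec <- function(...) {
  phantom_spec(grid_shape = c(80, 60, 40), spacing_mm = c(1, 1, 1),
               breast_offset_mm = 20, breast_semi_axes_mm = c(18, 16, 15),
               tumor_center_offset_mm = c(6, 3, 0), tumor_radius_mm = 6.2,
               ...)
}
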