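# Shared fixtures and independent oracles. Oracles are deliberately written
# as slow, literal loops so they stay independent of the vectorized package
# paths they check.

make_disc <- function(n, cr, cc, r) {
  m <- matrix(FALSE, n, n)
  m[(row(m) - cr)^2 + (col(m) - cc)^2 <= r^2] <- TRUE
  m
}

make_rect <- function(n, r1, r2, c1, c2) {
  m <- matrix(FALSE, n, n)
  m[r1:r2, c1:c2] <- TRUE
  m
}

# textbook per-pixel sRGB (D65) -> Lab, scalar arithmetic only
oracle_rgb_to_lab_px <- function(r, g, b) {
  lin <- function(v) if (v <= 0.04045) v / 12.92 else ((v + 0.055) / 1.055)^2.4
  rl <- lin(r / 255); gl <- lin(g / 255); bl <- lin(b / 255)
  X <- 0.4124564 * rl + 0.3575761 * gl + 0.1804375 * bl
  Y <- 0.2126729 * rl + 0.7151522 * gl + 0.0721750 * bl
  Z <- 0.0193339 * rl + 0.1191920 * gl + 0.9503041 * bl
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  fx <- f(X / 0.95047); fy <- f(Y / 1); fz <- f(Z / 1.08883)
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# exhaustive minimum within-group sum of squares over ALL 2-partitions
oracle_wss_2partition <- function(x) {
  n <- length(x)
  best <- Inf
  for (m in 1:(2^(n - 1) - 1)) {
    a <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
    if (!any(a) || all(a)) next
    w <- sum((x[a] - mean(x[a]))^2) + sum((x[!a] - mean(x[!a]))^2)
    if (w < best) best <- w
  }
  best
}

group_wss <- function(groups) sum(groups$stats$variance * groups$stats$size)

# full triple-loop scan of an amplitude matrix for above-threshold toroidal
# 8-neighbourhood local maxima (DC excluded)
oracle_scan_peaks <- function(amp, threshold) {
  nr <- nrow(amp); nc <- ncol(amp)
  hits <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (i == 1 && j == 1) next
    if (amp[i, j] <= threshold) next
    ismax <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- (i - 1 + di) %% nr + 1; jj <- (j - 1 + dj) %% nc + 1
      if (amp[ii, jj] > amp[i, j]) ismax <- FALSE
    }
    if (ismax) hits <- rbind(hits, c(i, j))
  }
  hits
}

# literal pairwise-distance defect scan: for every hull chord, every
# in-between boundary point's perpendicular depth
oracle_defects <- function(pts, depth_min) {
  n <- nrow(pts)
  h <- sort(grDevices::chull(pts[, 2], pts[, 1]))
  hs <- c(h, h[1] + n)
  out <- NULL
  for (k in seq_along(h)) {
    a <- hs[k]; b <- hs[k + 1]
    if (b - a < 2) next
    pa <- pts[(a - 1) %% n + 1, ]; pb <- pts[(b - 1) %% n + 1, ]
    L <- sqrt(sum((pb - pa)^2))
    if (L == 0) next
    dmax <- 0; arg <- NA
    for (t in (a + 1):(b - 1)) {
      p <- pts[(t - 1) %% n + 1, ]
      d <- abs((p[1] - pa[1]) * (pb[2] - pa[2]) -
                 (p[2] - pa[2]) * (pb[1] - pa[1])) / L
      if (d > dmax) { dmax <- d; arg <- (t - 1) %% n + 1 }
    }
    if (dmax >= depth_min) out <- c(out, arg)
  }
  out
}

# centred signed frequency of a 1-based DFT bin
oracle_signed_freq <- function(i, n) ifelse(i - 1 < n / 2, i - 1, i - 1 - n)

# brute-force plurality vote counter (ties -> not_determined)
oracle_vote_call <- function(tally) {
  mx <- max(tally)
  if (mx == 0 || sum(abs(tally - mx) < 1e-9) > 1) "not_determined"
  else names(tally)[which.max(tally)]
}

# stub classifier bank whose task predictions are fixed label vectors
# recycled over the samples
stub_models <- function(preds) {
  tasks <- c("ALLvsAML", "L1vsL2", "M2vs(M3&M5)", "M3vs(M2&M5)",
             "M5vs(M2&M3)", "M2vsM3vsM5", "subtype")
  models <- lapply(tasks, function(tn) {
    task <- leukemia_task(tn)
    lv <- unique(unname(task$map))
    labs <- preds[[tn]]
    list(task = task, levels = lv,
         fit = list(predict_scores = local({
           labs <- labs; lv <- lv
           function(newx) {
             p <- rep_len(labs, nrow(newx))
             s <- matrix(0, nrow(newx), length(lv),
                         dimnames = list(NULL, lv))
             s[cbind(seq_len(nrow(newx)), match(p, lv))] <- 1
             s
           }
         })))
  })
  names(models) <- tasks
  structure(list(models = models, learner = "stub", seed = 0,
                 columns = paste0("f", 1:3)),
            class = "diagnosis_models")
}

stub_samples <- function(n) {
  tibble::as_tibble(setNames(as.data.frame(matrix(0, n, 3)),
                             paste0("f", 1:3)))
}
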