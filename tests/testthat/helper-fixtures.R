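# Small two-sphere phantom and ROI layout used across the ROI tests:
# spheres well inside a 48x48 grid, ROIs clear of both spheres.
small_phantom <- function(tbr = 8) {
  spheres <- dplyr::bind_rows(
    sphere_spec("s22", c(-25, 0, 0), 22),
    sphere_spec("s28", c(25, 0, 0), 28)
  )
  phantom_spec(spheres, background_activity = 3, tbr_nominal = tbr)
}

small_rois <- function() rbind(c(0, 28), c(0, -28))

small_truth <- function(tbr = 8, dim = c(48, 48, 11)) {
  build_activity_map(small_phantom(tbr), dim = dim)
}

# naive forward selection oracle: direct residual-sum-of-squares search via
# the normal equations, independent of the package's fitting path
oracle_forward_selection <- function(data, response, candidates,
                                     f_enter = 4, min_delta_r2 = 0.01) {
  y <- data[[response]]
  sst <- sum((y - mean(y))^2)
  rss_of <- function(preds) {
    X <- cbind(1, as.matrix(data[preds]))
    b <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% b)^2)
  }
  chosen <- character()
  rss_cur <- sst
  repeat {
    remaining <- setdiff(candidates, chosen)
    if (!length(remaining)) break
    stats <- vapply(remaining, function(cand) {
      preds <- c(chosen, cand)
      if (qr(cbind(1, as.matrix(data[preds])))$rank < length(preds) + 1) {
        return(c(NA, NA))
      }
      rss <- rss_of(preds)
      df2 <- length(y) - length(preds) - 1
      c((rss_cur - rss) / (rss / df2), rss)
    }, numeric(2))
    if (all(is.na(stats[1, ]))) break
    best <- which.max(stats[1, ])
    dr2 <- (rss_cur - stats[2, best]) / sst
    if (is.na(stats[1, best]) || stats[1, best] <= f_enter ||
        dr2 < min_delta_r2) break
    chosen <- c(chosen, remaining[best])
    rss_cur <- stats[2, best]
  }
  chosen
}
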