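# Shared fixtures, built in code.

# small symmetric template used across tests
small_template <- function(n = 150) make_symmetric_template(n)

# a toy 2D landmark configuration: midline on x = 0, pairs at given
# horizontal distances / vertical offsets
toy_config_2d <- function(pairs, midline_x = 0) {
  # pairs: data.frame(name, lx, ly, rx, ry)
  pts <- rbind(
    data.frame(name = paste0(pairs$name, "_l"), x = pairs$lx, y = pairs$ly),
    data.frame(name = paste0(pairs$name, "_r"), x = pairs$rx, y = pairs$ry),
    data.frame(name = c("m1", "m2", "m3"), x = midline_x, y = c(-10, 0, 10)))
  landmark_config(pts,
                  data.frame(left = paste0(pairs$name, "_l"),
                             right = paste0(pairs$name, "_r")),
                  c("m1", "m2", "m3"))
}

# random rigid transform with bounded angle
random_rigid <- function(max_deg = 10, max_mm = 5) {
  rigid_transform(facefa:::rotation_about(stats::rnorm(3), stats::runif(1, -max_deg, max_deg)),
                  stats::runif(3, -max_mm, max_mm))
}

# independent closed-form (unweighted) rigid superimposition of X onto Y,
# written directly from the textbook SVD recipe
oracle_procrustes <- function(X, Y) {
  mx <- colMeans(X); my <- colMeans(Y)
  H <- t(sweep(X, 2, mx)) %*% sweep(Y, 2, my)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.numeric(my - R %*% mx))
}
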