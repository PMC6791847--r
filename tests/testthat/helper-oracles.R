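# Independent brute-force oracles and small fixture builders.
# Oracles use explicit double loops so they share no code path with the
# vectorised implementations they check.

brute_path_length <- function(p) {
  s <- 0
  for (i in 2:nrow(p)) s <- s + sqrt(sum((p[i, ] - p[i - 1, ])^2))
  s
}

brute_min_pair <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt(sum((a[i, ] - b[j, ])^2))
    if (d < best) best <- d
  }
  best
}

# index of the filament point minimising distance to any anchor point
brute_origin_index <- function(fp, anchor) {
  best <- Inf; bi <- NA_integer_
  for (i in seq_len(nrow(fp))) for (j in seq_len(nrow(anchor))) {
    d <- sqrt(sum((fp[i, ] - anchor[j, ])^2))
    if (d < best) { best <- d; bi <- i }
  }
  bi
}

# sup |ECDF_x - ECDF_y| by sweeping every pooled value
brute_ks_D <- function(x, y) {
  best <- 0
  for (t in c(x, y)) {
    d <- abs(sum(x <= t) / length(x) - sum(y <= t) / length(y))
    if (d > best) best <- d
  }
  best
}

random_rigid_motion <- function() {
  m <- matrix(rnorm(9), 3)
  R <- qr.Q(qr(m))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, 0, 50))
}

apply_motion <- function(p, mo) sweep(p %*% t(mo$R), 2, mo$t, "+")

random_filament <- function(n = 10, id = "f", scale = 30) {
  Filament(id, matrix(rnorm(3 * n, 0, scale), ncol = 3))
}

# a minimal quantifiable site: straight filaments rising from given origins,
# lateral-element points directly beneath them
toy_site <- function(origins, lengths = rep(50, nrow(origins)), siteId = "toy",
                     mtAxis = NULL) {
  fl <- lapply(seq_len(nrow(origins)), function(i) {
    o <- origins[i, ]
    Filament(sprintf("f%02d", i), rbind(o, o + c(0, 0, lengths[i] / 2),
                                        o + c(0, 0, lengths[i])))
  })
  le <- sweep(origins, 2, c(0, 0, 15))
  st <- list(lateral_element = StructurePointSet("lateral_element", le))
  if (!is.null(mtAxis))
    st$microtubule <- StructurePointSet("microtubule", mtAxis)
  AttachmentSiteModel(siteId = siteId, pixelSize = 1, structures = st,
                      filaments = fl,
                      microtubuleAxis = if (is.null(mtAxis)) matrix(0, 0, 3)
                                        else mtAxis)
}
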