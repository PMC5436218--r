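# Independent oracles used to cross-check the package's own routines.
# These deliberately use different algorithms from the implementation.

# Closed-form rigid superposition via Horn's quaternion method: returns the
# rotation matrix mapping centred `mob` onto centred `ref`.
horn_rotation <- function(mob, ref) {
  mob0 <- sweep(mob, 2L, colMeans(mob))
  ref0 <- sweep(ref, 2L, colMeans(ref))
  M <- t(mob0) %*% ref0
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4L, 4L)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1L]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), w^2 - x^2 - y^2 + z^2),
    3L, 3L)
  # return in row-vector convention: fitted = mob0 %*% R
  t(R)
}

# Brute-force point location: tests every shape directly with elementary
# half-plane / interval / sphere tests, then applies the priority order.
brute_locate <- function(pts, model) {
  pts <- matrix(pts, ncol = 3L)
  in_prism <- function(poly, z_lo, z_hi, p) {
    if (p[3] < z_lo || p[3] > z_hi) return(FALSE)
    n <- nrow(poly)
    sgn <- numeric(n)
    for (e in seq_len(n)) {
      a <- poly[e, ]; b <- poly[if (e == n) 1L else e + 1L, ]
      sgn[e] <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    }
    all(sgn >= -1e-12) || all(sgn <= 1e-12)
  }
  vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    for (m in model$monomers) for (ch in m$channels) {
      r <- ch$interior
      if (in_prism(r$poly, r$z_lo, r$z_hi, p)) return(r$label)
    }
    for (m in model$monomers) {
      r <- m$cavity
      if (in_prism(r$poly, r$z_lo, r$z_hi, p)) return(r$label)
    }
    for (m in model$monomers) if (!is.null(m$site)) {
      s <- m$site
      for (k in seq_along(s$radii))
        if (sum((p - s$centers[k, ])^2) <= s$radii[k]^2) return(s$label)
    }
    if (!is.null(model$footprint)) {
      r <- model$footprint
      if (in_prism(r$poly, r$z_lo, r$z_hi, p)) return("PROTEIN")
    }
    if (p[3] >= model$slab$z_lo && p[3] <= model$slab$z_hi) return("BULK")
    "OFF"
  }, character(1L))
}

# Brute-force excursion scanner over a label-side sequence: enumerates
# every maximal channel block and classifies it by its neighbours.
oracle_passages <- function(labels, times, min_dwell_ns = 1) {
  side <- ifelse(startsWith(labels, "CHANNEL_"), "channel",
                 ifelse(startsWith(labels, "CAVITY.") |
                          startsWith(labels, "SITE."), "cavity", "bulk"))
  stride <- if (length(times) > 1L) stats::median(diff(times)) else 0
  out <- list()
  i <- 1L
  n <- length(labels)
  while (i <= n) {
    if (side[i] != "channel") { i <- i + 1L; next }
    j <- i
    while (j < n && side[j + 1L] == "channel") j <- j + 1L
    block <- labels[i:j]
    counts <- table(block)
    best <- max(counts)
    cands <- names(counts)[counts == best]
    chan <- block[block %in% cands][1L]
    before <- if (i > 1L) side[i - 1L] else NA
    after <- if (j < n) side[j + 1L] else NA
    dwell <- (j - i + 1L) * stride
    rec <- NULL
    if (is.na(before) || is.na(after)) {
      rec <- list(channel = chan, completeness = "trapped", direction = NA)
    } else if (before != after) {
      rec <- list(channel = chan, completeness = "full",
                  direction = if (after == "cavity") "in" else "out")
    } else if (dwell >= min_dwell_ns) {
      rec <- list(channel = chan, completeness = "partial",
                  direction = if (before == "bulk") "in" else "out")
    }
    if (!is.null(rec)) out[[length(out) + 1L]] <- rec
    i <- j + 1L
  }
  out
}

# random label sequences over the toy label alphabet
random_label_sequence <- function(n, p_stay = 0.6) {
  alphabet <- c("BULK", "CAVITY.1", "CHANNEL_I.1", "CHANNEL_II.1",
                "CHANNEL_III.1", "SITE.1")
  lab <- character(n)
  lab[1] <- sample(alphabet, 1L)
  for (i in seq_len(n - 1L)) {
    lab[i + 1L] <- if (stats::runif(1) < p_stay) lab[i] else
      sample(alphabet, 1L)
  }
  lab
}

# build a qx_trace directly from labels (bypassing coordinates)
make_trace <- function(labels, stride_ns = 0.5, ligand = "L1",
                       species = "PLQ", z = NULL) {
  time <- seq(0, by = stride_ns, length.out = length(labels))
  if (is.null(z)) z <- rep(0, length(labels))
  quinex:::.new_trace(ligand, species, time, labels, z)
}
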