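# shared fixtures: tiny event tables, synthetic images, independent oracles

minimal_table <- function(n = 3L) {
  tibble::tibble(event_id = seq_len(n),
                 rsg_intensity = 10 * seq_len(n),
                 pi_intensity = 5 * seq_len(n))
}

# event_image without constructor overhead (trusted inputs in tests)
quick_image <- function(bf, rsg = bf, pi = bf, pixel_size = 1) {
  structure(list(channels = list(bf = bf, rsg = rsg, pi = pi),
                 pixel_size = pixel_size),
            class = "event_image")
}

# digitized filled ellipse mask: full axes 2a x 2b pixels, rotated by theta
ellipse_fixture <- function(n, a, b, theta = 0) {
  ctr <- (n + 1) / 2
  x <- matrix(rep(seq_len(n), each = n), n) - ctr
  y <- matrix(rep(seq_len(n), n), n) - ctr
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

# independent brute-force GLCM statistics: explicit loops over pixel pairs,
# no shared code with the package implementation
brute_glcm_stats <- function(mat, mask, g, levels) {
  v <- mat[mask]
  rng <- range(v)
  q <- matrix(NA_integer_, nrow(mat), ncol(mat))
  q[mask] <- if (diff(rng) == 0) 1L else
    pmin(as.integer((mat[mask] - rng[1]) / diff(rng) * levels) + 1L, levels)
  dirs <- list(c(0, g), c(-g, g), c(-g, 0), c(-g, -g))
  ent <- hom <- numeric(0)
  for (d in dirs) {
    counts <- matrix(0, levels, levels)
    for (r in seq_len(nrow(mat))) {
      for (cc in seq_len(ncol(mat))) {
        r2 <- r + d[1]; c2 <- cc + d[2]
        if (r2 >= 1 && r2 <= nrow(mat) && c2 >= 1 && c2 <= ncol(mat) &&
            !is.na(q[r, cc]) && !is.na(q[r2, c2])) {
          counts[q[r, cc], q[r2, c2]] <- counts[q[r, cc], q[r2, c2]] + 1
          counts[q[r2, c2], q[r, cc]] <- counts[q[r2, c2], q[r, cc]] + 1
        }
      }
    }
    if (sum(counts) == 0) return(NULL)
    p <- counts / sum(counts)
    nz <- p[p > 0]
    ent <- c(ent, -sum(nz * log2(nz)))
    hom <- c(hom, sum(p / (1 + abs(row(p) - col(p)))))
  }
  list(entropy_mean = mean(ent), entropy_std = sd(ent),
       homogeneity_mean = mean(hom), homogeneity_std = sd(hom))
}

# build a sorting_outcome with an exact number of growing wells/colonies
fixed_outcome <- function(k48, k72, medium = "broth", n = 24L,
                          subpopulation = "active") {
  stopifnot(k72 >= k48, k72 <= n)
  blank <- 0.04
  is_broth <- medium == "broth"
  od48 <- if (is_broth) {
    c(rep(blank + 0.5, k48), rep(blank + 0.01, n - k48))
  } else {
    rep(NA_real_, n)
  }
  od72 <- if (is_broth) {
    c(rep(blank + 0.8, k72), rep(blank + 0.01, n - k72))
  } else {
    rep(NA_real_, n)
  }
  cells <- tibble::tibble(
    subpopulation = subpopulation, medium = medium, cell = seq_len(n),
    grew = seq_len(n) <= k72, lag_h = 20,
    od600_48h = od48, od600_72h = od72,
    colony_48h = !is_broth & seq_len(n) <= k48,
    colony_72h = !is_broth & seq_len(n) <= k72
  )
  structure(list(cells = cells, n_sorted = n, od_blank = blank,
                 od_threshold = 0.1),
            class = "sorting_outcome")
}
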