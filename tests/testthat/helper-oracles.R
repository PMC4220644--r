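# Independent brute-force oracles. Deliberately naive: plain loops over
# pixels/pairs, no shared code with the implementation beyond shared
# definitional constants (offset convention, circularity formula).

naive_otsu <- function(gray) {
  v <- as.vector(gray)
  best <- -Inf; best_t <- 0L
  for (t in 0:254) {
    a <- v[v <= t]; b <- v[v > t]
    if (!length(a) || !length(b)) next
    w0 <- length(a) / length(v)
    sb2 <- w0 * (1 - w0) * (mean(a) - mean(b))^2
    if (sb2 > best + 1e-12) { best <- sb2; best_t <- t }
  }
  best_t
}

naive_glcm <- function(gray, distance, angle, levels, symmetric) {
  dd <- switch(as.character(angle),
               "0" = c(0, distance), "45" = c(-distance, distance),
               "90" = c(-distance, 0), "135" = c(-distance, -distance))
  P <- matrix(0, levels, levels)
  nr <- nrow(gray); nc <- ncol(gray)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + dd[1]; c2 <- c + dd[2]
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    i <- gray[r, c] + 1L; j <- gray[r2, c2] + 1L
    P[i, j] <- P[i, j] + 1
    if (symmetric) P[j, i] <- P[j, i] + 1
  }
  P / sum(P)
}

naive_texture <- function(P) {
  n <- nrow(P)
  ent <- 0; asm <- 0; varr <- 0; sij <- 0
  px <- numeric(n); py <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    p <- P[i, j]
    if (p > 0) ent <- ent - p * log(p)
    asm <- asm + p^2
    px[i] <- px[i] + p; py[j] <- py[j] + p
    sij <- sij + (i - 1) * (j - 1) * p
  }
  mux <- sum((seq_len(n) - 1) * px); muy <- sum((seq_len(n) - 1) * py)
  sdx <- sqrt(sum((seq_len(n) - 1 - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(n) - 1 - muy)^2 * py))
  for (i in seq_len(n)) varr <- varr + sum((i - 1 - mux)^2 * P[i, ])
  corr <- if (sdx * sdy > 0) (sij - mux * muy) / (sdx * sdy) else 0
  list(entropy = ent, asm = asm, variance = varr, correlation = corr)
}

naive_box_count <- function(pattern, size, origin) {
  keys <- character(0)
  for (r in seq_len(nrow(pattern))) for (c in seq_len(ncol(pattern))) {
    if (!pattern[r, c]) next
    keys <- c(keys, paste(floor((r - 1 - origin[1]) / size),
                          floor((c - 1 - origin[2]) / size)))
  }
  length(unique(keys))
}

# masses of every box fully inside the image, including empty boxes
naive_box_masses <- function(pattern, size, origin) {
  nr <- nrow(pattern); nc <- ncol(pattern)
  masses <- numeric(0)
  r0 <- origin[1] + 1
  while (r0 + size - 1 <= nr) {
    c0 <- origin[2] + 1
    while (c0 + size - 1 <= nc) {
      masses <- c(masses, sum(pattern[r0:(r0 + size - 1), c0:(c0 + size - 1)]))
      c0 <- c0 + size
    }
    r0 <- r0 + size
  }
  masses
}

naive_lacunarity <- function(pattern, sizes, origins, mode = "cv") {
  cvs <- numeric(0)
  for (o in seq_len(nrow(origins))) for (s in sizes) {
    m <- naive_box_masses(pattern, s, origins[o, ] %% s)
    if (!length(m)) next
    mu <- mean(m)
    if (mu == 0) next
    sg <- sqrt(mean((m - mu)^2))
    cvs <- c(cvs, if (mode == "cv") sg / mu else (sg / mu)^2)
  }
  mean(cvs)
}

# flood-fill labeling + per-component predicate check
naive_flood_label <- function(pattern, connectivity) {
  nr <- nrow(pattern); nc <- ncol(pattern)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (c in seq_len(nc)) for (r in seq_len(nr)) {
    if (!pattern[r, c] || lab[r, c] > 0) next
    cur <- cur + 1L
    queue <- list(c(r, c)); lab[r, c] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        r2 <- p[1] + nb[k, 1]; c2 <- p[2] + nb[k, 2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (pattern[r2, c2] && lab[r2, c2] == 0) {
          lab[r2, c2] <- cur
          queue[[length(queue) + 1]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# transition-count Crofton perimeter of the single component mask == lab
naive_crofton <- function(comp) {
  count_line <- function(v) sum(abs(diff(c(0, as.integer(v), 0))))
  t0 <- sum(vapply(seq_len(nrow(comp)), function(r) count_line(comp[r, ]), 1))
  t90 <- sum(vapply(seq_len(ncol(comp)), function(c) count_line(comp[, c]), 1))
  nr <- nrow(comp); nc <- ncol(comp)
  t135 <- 0; t45 <- 0
  for (d in (-nr + 1):(nc - 1)) {   # main-direction diagonals
    rs <- seq_len(nr); cs <- rs + d
    ok <- cs >= 1 & cs <= nc
    if (any(ok)) t135 <- t135 + count_line(comp[cbind(rs[ok], cs[ok])])
  }
  for (d in 2:(nr + nc)) {          # anti-diagonals
    rs <- seq_len(nr); cs <- d - rs
    ok <- cs >= 1 & cs <= nc
    if (any(ok)) t45 <- t45 + count_line(comp[cbind(rs[ok], cs[ok])])
  }
  (pi / 8) * (t0 + t90 + (t45 + t135) / sqrt(2))
}

naive_geometric_filter <- function(pattern, config) {
  lab <- naive_flood_label(pattern, config$connectivity)
  out <- pattern
  if (max(lab) == 0) return(out)
  for (k in seq_len(max(lab))) {
    comp <- lab == k
    a <- sum(comp)
    circ <- min(1, 4 * pi * a / naive_crofton(comp)^2)
    if (a < config$min_area || a > config$max_area ||
        circ < config$min_circularity || circ > config$max_circularity)
      out[comp] <- FALSE
  }
  out
}

naive_morisita <- function(pattern, grid_rows, grid_cols) {
  ch <- nrow(pattern) %/% grid_rows
  cw <- ncol(pattern) %/% grid_cols
  counts <- matrix(0, grid_rows, grid_cols)
  for (r in seq_len(grid_rows * ch)) for (c in seq_len(grid_cols * cw)) {
    if (pattern[r, c])
      counts[(r - 1) %/% ch + 1, (c - 1) %/% cw + 1] <-
        counts[(r - 1) %/% ch + 1, (c - 1) %/% cw + 1] + 1
  }
  N <- sum(counts); n <- grid_rows * grid_cols
  list(id = n * (sum(counts^2) - N) / (N * (N - 1)),
       counts = as.vector(t(counts)))   # row-major
}

naive_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

naive_anova_F <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  k <- length(groups); N <- length(all)
  (ssb / (k - 1)) / (ssw / (N - k))
}

random_pattern <- function(nr, nc, p = 0.3) matrix(runif(nr * nc) < p, nr, nc)

random_gray <- function(nr, nc, levels = 16L) {
  matrix(sample.int(levels, nr * nc, replace = TRUE) - 1L, nr, nc)
}
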