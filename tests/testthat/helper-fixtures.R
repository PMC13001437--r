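# fixtures and independent brute-force oracles shared across test files

# binary mask with a filled rectangle
rect_mask <- function(nrow, ncol, rows, cols) {
  m <- matrix(0L, nrow, ncol)
  m[rows, cols] <- 1L
  m
}

# band between two parallel lines of slope tan(theta), vertical width h
tilted_band <- function(nrow, ncol, theta_deg, y_top, h) {
  s <- tan(theta_deg * pi / 180)
  m <- matrix(0L, nrow, ncol)
  for (x in seq_len(ncol)) {
    top <- y_top + s * (x - 1)
    ys <- which(seq_len(nrow) >= top & seq_len(nrow) < top + h)
    m[ys, x] <- 1L
  }
  m
}

# wedge: per-column height ramping linearly from h0 to h1, flat top
wedge_mask <- function(nrow, ncol, h0, h1, y_top = 5) {
  m <- matrix(0L, nrow, ncol)
  hs <- round(seq(h0, h1, length.out = ncol))
  for (x in seq_len(ncol)) m[y_top:(y_top + hs[x] - 1L), x] <- 1L
  list(mask = m, heights = hs)
}

# 8-connected component labeling by explicit BFS flood fill (oracle,
# independent of the compiled path)
flood_fill_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (c in seq_len(nc)) for (r in seq_len(nr)) {
    if (mask[r, c] == 0 || lab[r, c] != 0L) next
    cur <- cur + 1L
    queue <- list(c(r, c)); lab[r, c] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr < 1 || cc < 1 || rr > nr || cc > nc) next
        if (mask[rr, cc] != 0 && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# junction-event count oracle: neighbor counting + merging of 8-adjacent
# junction pixels, written independently of the package internals
junction_count_oracle <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  jx <- matrix(0L, nr, nc)
  for (c in seq_len(nc)) for (r in seq_len(nr)) {
    if (skel[r, c] == 0) next
    n <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && cc >= 1 && rr <= nr && cc <= nc && skel[rr, cc] != 0)
        n <- n + 1L
    }
    if (n >= 3L) jx[r, c] <- 1L
  }
  max(flood_fill_label(jx))
}

# exhaustive-search distance to nearest background pixel (oracle for
# thickness on small fixtures); edges beyond the matrix count as background
nearest_bg_dist_oracle <- function(mask, r, c) {
  bg <- which(mask == 0, arr.ind = TRUE)
  d_in <- if (nrow(bg)) min(sqrt((bg[, 1] - r)^2 + (bg[, 2] - c)^2)) else Inf
  d_edge <- min(r, c, nrow(mask) - r + 1, ncol(mask) - c + 1)
  min(d_in, d_edge)
}

# O(n^2) Cliff's delta by explicit double loop (oracle)
cliffs_delta_oracle <- function(x, y) {
  gt <- 0L; lt <- 0L
  for (xi in x) for (yj in y) {
    if (xi > yj) gt <- gt + 1L
    if (xi < yj) lt <- lt + 1L
  }
  (gt - lt) / (length(x) * length(y))
}

# brute-force Benjamini-Hochberg step-up (oracle)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# mean silhouette width for a 2-way partition (oracle for cluster
# separation checks)
silhouette_oracle <- function(z, labels) {
  d <- as.matrix(dist(z))
  n <- nrow(z)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]; own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- mean(d[i, labels != labels[i]])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# small flat 8-layer phantom crop used in metric and feature tests
flat_crop_config <- function(width = 256L, height = 400L) {
  phantom_config(width = width, height = height, curvature_amplitude = 0,
                 top_margin = 60,
                 base_thickness = c(IPL = 50, INL = 30, OPL = 15, ONL = 60,
                                    ELM = 8, ISOS = 25, RPE = 12, CHR = 40))
}

# synthetic per-layer QC summaries: n_multi layers split into two domains
# with the given largest-domain ratio, the rest intact
qc_summaries <- function(n_layers_present = 8L, n_multi = 0L, ratio = 1,
                         bifurcations = 0L) {
  sc <- layer_scheme()
  out <- list()
  for (i in seq_len(8L)) {
    ly <- sc$layers[i]
    present <- i <= n_layers_present
    multi <- present && i <= n_multi
    out[[ly]] <- list(area = if (present) 1000L else 0L,
                      n_domains = if (!present) 0L else if (multi) 2L else 1L,
                      largest_ratio = if (multi) ratio else 1,
                      bifurcations = if (i == 1L) bifurcations else 0L)
  }
  out
}
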