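# Fixtures built in code: small label masks, rasterised shapes and a
# scaled-down simulation preset used throughout the suite.

# simulation preset with small fields, sparse wells and smaller cells
# for fast tests
test_sim_params <- function(...) {
  p <- simulation_params(...)
  p$image_shape <- c(320L, 320L)
  p$n_fields <- 3L
  for (nm in names(p$conditions)) {
    p$conditions[[nm]]$expected_attached_cells <-
      p$conditions[[nm]]$expected_attached_cells / 4
    p$conditions[[nm]]$cell_area_um2[["meanlog"]] <-
      p$conditions[[nm]]$cell_area_um2[["meanlog"]] - log(2)
    p$conditions[[nm]]$nucleus_area_um2[["meanlog"]] <-
      p$conditions[[nm]]$nucleus_area_um2[["meanlog"]] - log(1.6)
  }
  p
}

disk_mask <- function(r, pad = 5L, label = 1L) {
  n <- 2L * (r + pad) + 1L
  c0 <- r + pad + 1L
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if ((i - c0)^2 + (j - c0)^2 <= r^2) m[i, j] <- label
    }
  }
  m
}

ellipse_mask <- function(a, b, angle = 0, pad = 5L, label = 1L) {
  n <- 2L * (ceiling(a) + pad) + 1L
  c0 <- ceiling(a) + pad + 1L
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      u <- (i - c0) * cos(angle) + (j - c0) * sin(angle)
      v <- -(i - c0) * sin(angle) + (j - c0) * cos(angle)
      if ((u / a)^2 + (v / b)^2 <= 1) m[i, j] <- label
    }
  }
  m
}

# random label mask: stamped rectangles with distinct labels, relabelled
# consecutively; some touch, some are isolated
random_label_mask <- function(n_obj = 6L, dim = c(60L, 60L)) {
  m <- matrix(0L, dim[1], dim[2])
  for (k in seq_len(n_obj)) {
    w <- sample(3:9, 1); h <- sample(3:9, 1)
    x <- sample(seq_len(dim[1] - w), 1)
    y <- sample(seq_len(dim[2] - h), 1)
    m[x:(x + w), y:(y + h)] <- k
  }
  phenoplate:::relabel_consecutive(m)
}

# brute-force clump oracle: pairwise min Chebyshev distance <= 2, then
# connected components by BFS over the adjacency graph
oracle_clumps <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) return(list())
  pix <- lapply(ids, function(k) which(lab == k, arr.ind = TRUE))
  n <- length(ids)
  adj <- matrix(FALSE, n, n)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      pa <- pix[[a]]; pb <- pix[[b]]
      touch <- FALSE
      for (i in seq_len(nrow(pa))) {
        d <- pmax(abs(pb[, 1] - pa[i, 1]), abs(pb[, 2] - pa[i, 2]))
        if (any(d <= 2L)) { touch <- TRUE; break }
      }
      adj[a, b] <- adj[b, a] <- touch
    }
  }
  comp <- rep(0L, n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  lapply(seq_len(cur), function(k) ids[comp == k])
}

# random object table with values straddling every filter threshold
random_object_table <- function(n, seed = 1L) {
  set.seed(seed)
  as_object_table(tibble::tibble(
    plate = "p1", well = "B02", field = 1L, object = seq_len(n),
    nucleus_area_um2 = runif(n, 10, 800),
    nucleus_roundness = runif(n, 0.2, 1),
    nucleus_width_to_length = runif(n, 0.2, 1),
    cell_area_um2 = runif(n, 100, 9000),
    cell_roundness = runif(n, 0.2, 1),
    cell_width_to_length = runif(n, 0.2, 1),
    dapi_median = runif(n, 0, 12000),
    edu488_median = runif(n, 0, 12000),
    brightfield_median = runif(n, -5, 100),
    n_per_clump = NA_integer_, qc_stage = "nuclei"))
}

# centroids of a label mask in the simulator's 0-based convention
mask_centroids <- function(mask) {
  lab <- mask$labels
  idx <- which(lab > 0L)
  nr <- nrow(lab)
  xs <- ((idx - 1L) %% nr) + 1L
  ys <- ((idx - 1L) %/% nr) + 1L
  data.frame(object = as.integer(names(tapply(xs, lab[idx], mean))),
             x = as.numeric(tapply(xs, lab[idx], mean)) - 1,
             y = as.numeric(tapply(ys, lab[idx], mean)) - 1)
}

# greedy centroid matching of detections against ground truth
match_detections <- function(truth, det, max_dist) {
  used <- rep(FALSE, nrow(det))
  tp <- 0L
  for (i in seq_len(nrow(truth))) {
    if (!nrow(det)) break
    d <- sqrt((det$x - truth$x_px[i])^2 + (det$y - truth$y_px[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= max_dist) { tp <- tp + 1L; used[j] <- TRUE }
  }
  list(tp = tp, n_truth = nrow(truth), n_det = nrow(det))
}
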