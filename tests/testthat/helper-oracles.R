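# Brute-force reference implementations used as independent oracles.
# Morphology is realized by explicit structuring-element shifts and
# connected components by graph components (igraph), fully independent of
# the package's distance-transform / flood-fill implementation.

ball_offsets <- function(r) {
  g <- expand.grid(d1 = -r:r, d2 = -r:r, d3 = -r:r)
  as.matrix(g[g$d1^2 + g$d2^2 + g$d3^2 <= r^2, , drop = FALSE])
}

shift3 <- function(m, off, fill = FALSE) {
  d <- dim(m)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    o <- off[k]
    if (o >= 0) { dst[[k]] <- seq_len(d[k] - o) + o; src[[k]] <- seq_len(d[k] - o) }
    else { dst[[k]] <- seq_len(d[k] + o); src[[k]] <- seq_len(d[k] + o) - o }
    if (length(dst[[k]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

bf_dilate <- function(m, r) {
  off <- ball_offsets(r)
  out <- array(FALSE, dim(m))
  for (i in seq_len(nrow(off))) out <- out | shift3(m, off[i, ])
  out
}

# border: what off-grid voxels count as during erosion
bf_erode <- function(m, r, border_fill = FALSE) {
  off <- ball_offsets(r)
  out <- array(TRUE, dim(m))
  for (i in seq_len(nrow(off))) out <- out & shift3(m, off[i, ], fill = border_fill)
  out
}

# largest connected component via igraph on the voxel adjacency graph
bf_largest_component <- function(m, connectivity) {
  idx <- which(m)
  if (length(idx) == 0L) return(m)
  d <- dim(m)
  comp_id <- integer(length(m))
  comp_id[idx] <- seq_along(idx)
  ai <- arrayInd(idx, d)
  offs <- ball_offsets(if (connectivity == 6L) 1L else 1.8)
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 26L) {
    g <- expand.grid(d1 = -1:1, d2 = -1:1, d3 = -1:1)
    offs <- as.matrix(g[rowSums(abs(g)) > 0, , drop = FALSE])
  }
  edges <- NULL
  for (i in seq_len(nrow(offs))) {
    nb <- sweep(ai, 2L, offs[i, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] +
      (nb[ok, 3] - 1L) * d[1] * d[2]
    sel <- m[lin]
    edges <- rbind(edges, cbind(comp_id[idx[ok][sel]], comp_id[lin[sel]]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0)
    g <- igraph::add_edges(g, t(edges))
  cl <- igraph::components(g)
  keep <- idx[cl$membership == which.max(cl$csize)]
  out <- array(FALSE, d)
  out[keep] <- TRUE
  out
}

# keep only the largest background component (fill all others)
bf_fill_holes <- function(m, bg_connectivity = 6L) {
  if (!any(!m)) return(m)
  !bf_largest_component(!m, bg_connectivity)
}

# brute-force mirror of the iterative binary segmentation filter
bf_iterative_filter <- function(m, open_max, close_max) {
  for (r in seq_len(max(open_max, close_max))) {
    if (r <= open_max) {
      er <- bf_erode(m, r, border_fill = TRUE)
      if (!any(er)) return(er)
      m <- bf_dilate(bf_largest_component(er, 26L), r)
    }
    if (r <= close_max) {
      pad <- r
      d <- dim(m)
      big <- array(FALSE, d + 2L * pad)
      big[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- m
      big <- bf_fill_holes(bf_dilate(big, r), 6L)
      big <- bf_erode(big, r, border_fill = FALSE)
      m <- big[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3]),
               drop = FALSE]
    }
  }
  m
}

# solid ball fixture with an internal cavity and a distant speck
speck_cavity_fixture <- function(n = 48L, ball_r = n * 0.3, cavity_r = 4) {
  cc <- (n + 1) / 2
  D <- array(0, c(n, n, n))
  pl <- outer(((1:n) - cc)^2, ((1:n) - cc)^2, "+")
  for (z in 1:n) D[z, , ] <- sqrt(pl + (z - cc)^2)
  fx <- D <= ball_r
  fx[D <= cavity_r] <- FALSE
  fx[2, 2, 2] <- TRUE
  list(mask = fx, dist = D, ball_r = ball_r, cavity_r = cavity_r)
}

# shared desk-scale phantom/training configuration for smoke tests
smoke_phantom_spec <- function(seed) {
  phantom_spec(n_slices = 6L, in_plane = 64L, outer_radius_mm = 1.5,
               cortical_thickness_mm = 0.6, pore_count = 2L, seed = seed)
}

smoke_sample <- function(seed) {
  ph <- generate_phantom(smoke_phantom_spec(seed))
  list(volume = pad_in_plane(standardize(ph$volume)), seg = ph$truth,
       phantom = ph)
}

smoke_unet_config <- function() {
  unet_config(base_channels = 12L, depth = 2L, groupnorm_groups = 4L,
              dropout_p = 0.05)
}

smoke_training_config <- function(seed = 17L) {
  training_config(epochs_halfcycle = 5L, epochs_converge = 2L,
                  lr_min = 2e-4, lr_max = 2e-3, seed = seed)
}
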