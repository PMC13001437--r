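#' Skeletonize a binary mask
#'
#' Deterministic Zhang-Suen thinning to a 1-pixel-wide, 8-connected medial
#' skeleton, followed by a minimal-skeleton reduction that removes
#' staircase elbows and residual 2x2 blocks (sequential deletion of
#' connectivity-preserving non-endpoint pixels). Implemented in compiled
#' code; pixels outside the image are treated as background.
#'
#' @param mask binary matrix (0/1 or logical), rows = y, columns = x.
#' @return integer 0/1 matrix of the same shape.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  sk <- .cpp_thin(matrix(as.integer(mask != 0), nrow = nrow(mask)))
  .cpp_skel_cleanup(sk)
}

#' Label 8-connected components
#'
#' @param mask binary matrix.
#' @return integer matrix; background 0, components numbered 1..k in
#'   column-major first-seen order.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  .cpp_label8(matrix(as.integer(mask != 0), nrow = nrow(mask)))
}

# order the pixels of one junction-free skeleton branch into a path by
# walking from an endpoint (or from the first pixel for a closed loop)
.trace_branch <- function(coords) {
  n <- nrow(coords)
  if (n <= 2L) return(coords)
  adj <- (abs(outer(coords[, 1], coords[, 1], "-")) <= 1L) &
         (abs(outer(coords[, 2], coords[, 2], "-")) <= 1L)
  diag(adj) <- FALSE
  deg <- rowSums(adj)
  start <- which(deg <= 1L)
  start <- if (length(start)) start[1L] else 1L
  order_idx <- integer(n)
  visited <- logical(n)
  cur <- start
  for (i in seq_len(n)) {
    order_idx[i] <- cur
    visited[cur] <- TRUE
    nxt <- which(adj[cur, ] & !visited)
    if (!length(nxt)) break
    cur <- nxt[1L]
  }
  coords[order_idx[order_idx != 0L], , drop = FALSE]
}

# Remove skeleton spurs that are thinning artifacts rather than anatomy:
# endpoint branches shorter than min_spur that terminate at a junction
# (staircase noise stubs). The walk is capped at min_spur pixels, so long
# structural branches are never touched.
.prune_spurs <- function(sk, min_spur, max_iter = 10L) {
  for (it in seq_len(max_iter)) {
    ncnt <- .cpp_neighbor_count(sk)
    ends <- which(sk != 0L & ncnt == 1L, arr.ind = TRUE)
    if (nrow(ends) == 0L) break
    removed <- FALSE
    for (e in seq_len(nrow(ends))) {
      r <- ends[e, 1]; c <- ends[e, 2]
      if (sk[r, c] == 0L) next                     # already pruned this pass
      path <- matrix(c(r, c), ncol = 2L)
      junction <- FALSE
      while (nrow(path) < min_spur) {
        nb <- expand.grid(dr = -1:1, dc = -1:1)
        nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
        rr <- r + nb$dr; cc <- c + nb$dc
        ok <- rr >= 1 & rr <= nrow(sk) & cc >= 1 & cc <= ncol(sk)
        rr <- rr[ok]; cc <- cc[ok]
        on <- sk[cbind(rr, cc)] != 0L
        rr <- rr[on]; cc <- cc[on]
        seen <- paste(rr, cc) %in% paste(path[, 1], path[, 2])
        rr <- rr[!seen]; cc <- cc[!seen]
        if (length(rr) == 0L) break                # open end, keep
        if (length(rr) > 1L || ncnt[rr[1], cc[1]] >= 3L) {
          junction <- TRUE                         # reached a branch point
          break
        }
        r <- rr[1]; c <- cc[1]
        path <- rbind(path, c(r, c))
      }
      if (junction && nrow(path) < min_spur) {
        sk[path] <- 0L
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  sk
}

#' Per-layer medial-axis skeleton with junctions and branches
#'
#' Skeletonizes a (possibly multi-component) binary layer mask, prunes
#' artifactual spurs (see Details), identifies junction pixels (skeleton
#' pixels with 3 or more skeleton neighbors under 8-connectivity), merges
#' 8-adjacent junction pixels into single junction events, and decomposes
#' the remainder into ordered branch paths.
#'
#' @details Thinning a pixelated curved band can leave few-pixel artifact
#' spurs; endpoint branches terminating at a junction are pruned when
#' shorter than `min_spur` pixels. Longer structural spurs (true
#' bifurcations) are unaffected. Where a layer runs off the left/right
#' image edge, the cut would make the medial axis grow diagonal corner
#' tails; with `extend_x` the mask is extended sideways by replicating its
#' edge columns before thinning (matching [local_thickness()]), keeping the
#' axis centered across the whole window.
#'
#' @param layer_mask binary matrix for one layer.
#' @param layer optional layer name carried on the result.
#' @param prune prune artifact spurs (default TRUE).
#' @param min_spur minimum surviving spur length, px.
#' @param extend_x treat the left/right image edges as tissue cuts (see
#'   Details).
#' @return object of class `layer_skeleton`: list with `layer`, `skeleton`
#'   (0/1 matrix), `pixels` (data frame x, y), `junctions` (data frame
#'   x, y of junction pixels), `n_junction_events`, and `branches` (list of
#'   ordered data frames x, y).
#' @export
layer_skeleton <- function(layer_mask, layer = NA_character_, prune = TRUE,
                           min_spur = 5L, extend_x = TRUE) {
  m <- matrix(as.integer(layer_mask != 0), nrow = nrow(layer_mask))
  if (extend_x && any(m != 0L)) {
    pad <- ceiling(nrow(m) / 2) + 1L
    mp <- cbind(m[, rep(1L, pad), drop = FALSE], m,
                m[, rep(ncol(m), pad), drop = FALSE])
    sk <- skeletonize(mp)[, (pad + 1L):(pad + ncol(m)), drop = FALSE]
    sk <- .cpp_skel_cleanup(sk)        # re-minimalize after the crop-back
  } else {
    sk <- skeletonize(m)
  }
  if (prune && any(sk != 0L))
    sk <- .prune_spurs(sk, min_spur)
  idx <- which(sk != 0L, arr.ind = TRUE)           # (row, col)
  if (nrow(idx) == 0L)
    return(structure(list(layer = layer, skeleton = sk,
                          pixels = data.frame(x = integer(), y = integer()),
                          junctions = data.frame(x = integer(),
                                                 y = integer()),
                          n_junction_events = 0L, branches = list()),
                     class = "layer_skeleton"))
  ncnt <- .cpp_neighbor_count(sk)
  jmask <- sk
  jmask[!(sk != 0L & ncnt >= 3L)] <- 0L
  jidx <- which(jmask != 0L, arr.ind = TRUE)
  n_events <- if (nrow(jidx)) max(.cpp_label8(jmask)) else 0L

  branch_mask <- sk
  branch_mask[jmask != 0L] <- 0L
  blab <- .cpp_label8(branch_mask)
  branches <- list()
  if (max(blab) > 0L) {
    bidx <- which(blab != 0L, arr.ind = TRUE)
    labs <- blab[bidx]
    for (b in seq_len(max(blab))) {
      co <- bidx[labs == b, , drop = FALSE]
      co <- .trace_branch(co)
      branches[[b]] <- data.frame(x = unname(co[, 2]), y = unname(co[, 1]))
    }
  }
  structure(list(layer = layer, skeleton = sk,
                 pixels = data.frame(x = unname(idx[, 2]),
                                     y = unname(idx[, 1])),
                 junctions = data.frame(x = unname(jidx[, 2]),
                                        y = unname(jidx[, 1])),
                 n_junction_events = n_events, branches = branches),
            class = "layer_skeleton")
}

#' Count skeleton bifurcations
#'
#' Number of junction events along a layer's medial axis, after merging
#' 8-adjacent junction pixels into single events.
#'
#' @param skel a [layer_skeleton()].
#' @return integer count.
#' @export
count_bifurcations <- function(skel) {
  stopifnot(inherits(skel, "layer_skeleton"))
  skel$n_junction_events
}
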