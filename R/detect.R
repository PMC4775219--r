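#' Detect bead particles in an image
#'
#' Threshold (Otsu by default), label connected components
#' (8-connectivity), drop components touching the image border, and filter
#' by area and circularity. Circularity is `4 * pi * A / P^2` with the
#' perimeter measured on the component's polygonal (chain) boundary and the
#' value capped at 1 (the ImageJ convention; rasterized disks would
#' otherwise exceed 1).
#'
#' @param image 2-D numeric matrix.
#' @param min_area,max_area component area filter, px.
#' @param circ_min,circ_max circularity filter.
#' @param threshold intensity threshold; `NULL` picks it by Otsu's method.
#' @return data.frame with one row per accepted particle: `label`, `area`,
#'   `perimeter`, `circularity`, `cx`, `cy`.
#' @export
detect_beads <- function(image, min_area = 400, max_area = 15000,
                         circ_min = 0.60, circ_max = 1.00,
                         threshold = NULL) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a 2-D numeric matrix")
  empty <- data.frame(label = integer(), area = numeric(),
                      perimeter = numeric(), circularity = numeric(),
                      cx = numeric(), cy = numeric())
  mx <- max(image)
  if (mx <= 0) return(empty)
  if (is.null(threshold))
    threshold <- EBImage::otsu(EBImage::Image(image / mx), range = c(0, 1),
                               levels = 65536) * mx
  bw <- image > threshold
  if (!any(bw)) return(empty)
  labels <- label_components_8(bw)
  ids <- seq_len(max(labels))
  # border exclusion
  border <- unique(c(labels[1, ], labels[nrow(labels), ],
                     labels[, 1], labels[, ncol(labels)]))
  keep <- setdiff(ids, border)
  if (!length(keep)) return(empty)
  contours <- EBImage::ocontour(labels)
  rows <- lapply(keep, function(id) {
    px <- which(labels == id, arr.ind = TRUE)
    area <- nrow(px)
    oc <- contours[[id]]
    per <- if (nrow(oc) >= 2) {
      p <- rbind(oc, oc[1, , drop = FALSE])
      sum(sqrt(rowSums(diff(p)^2)))
    } else 1
    circ <- min(4 * pi * area / per^2, 1)
    data.frame(label = id, area = area, perimeter = per, circularity = circ,
               cx = mean(px[, 1]), cy = mean(px[, 2]))
  })
  out <- do.call(rbind, rows)
  out <- out[out$area >= min_area & out$area <= max_area &
               out$circularity >= circ_min & out$circularity <= circ_max, ]
  rownames(out) <- NULL
  out
}

# 8-connectivity connected-component labeling on a logical matrix, via
# connected components of the pixel-adjacency graph.
label_components_8 <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  idx <- which(bw)
  if (!length(idx)) return(matrix(0L, nr, nc))
  ord <- integer(nr * nc)
  ord[idx] <- seq_along(idx)
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- row + off[1]; c2 <- col + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    src <- idx[ok]
    fg <- bw[nb]
    if (any(fg))
      edges <- c(edges, rbind(ord[src[fg]], ord[nb[fg]]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  membership <- igraph::components(g)$membership
  labels <- matrix(0L, nr, nc)
  labels[idx] <- as.integer(membership)
  labels
}
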