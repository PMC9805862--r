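#' Connected-component labeling of 3D masks
#'
#' Labels the connected components of a logical 3D array under 6-, 18- or
#' 26-neighbor connectivity (18 = faces + edges, the convention of common
#' neuroimaging toolchains).
#'
#' @param mask Logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return List with `labels` (integer 3D array, 0 = background) and `sizes`
#'   (integer vector, one entry per component, labelled in decreasing size).
#' @export
label_clusters <- function(mask, connectivity = 18) {
  stopifnot(connectivity %in% c(6, 18, 26))
  dims <- dim(mask)
  stopifnot(length(dims) == 3)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(off != 0)
  off <- off[nz > 0 & nz <= switch(as.character(connectivity),
                                   `6` = 1, `18` = 2, `26` = 3), ,
             drop = FALSE]
  labels <- array(0L, dim = dims)
  vox <- which(mask, arr.ind = TRUE)
  if (nrow(vox) == 0) return(list(labels = labels, sizes = integer(0)))
  pending <- array(FALSE, dim = dims)
  pending[mask] <- TRUE
  sizes <- integer(0)
  lab <- 0L
  for (i in seq_len(nrow(vox))) {
    p0 <- vox[i, ]
    if (!pending[p0[1], p0[2], p0[3]]) next
    lab <- lab + 1L
    stack <- matrix(p0, nrow = 1)
    pending[p0[1], p0[2], p0[3]] <- FALSE
    count <- 0L
    while (nrow(stack) > 0) {
      p <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      labels[p[1], p[2], p[3]] <- lab
      count <- count + 1L
      nb <- sweep(off, 2, p, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      if (nrow(nb) > 0) {
        is_pend <- pending[nb]
        nb <- nb[is_pend, , drop = FALSE]
        if (nrow(nb) > 0) {
          pending[nb] <- FALSE
          stack <- rbind(stack, nb)
        }
      }
    }
    sizes <- c(sizes, count)
  }
  # relabel in decreasing size order for stable reporting
  ord <- order(sizes, decreasing = TRUE)
  remap <- integer(length(sizes))
  remap[ord] <- seq_along(sizes)
  labels[labels > 0] <- remap[labels[labels > 0]]
  list(labels = labels, sizes = sizes[ord])
}
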