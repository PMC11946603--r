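#' Label connected components of a binary matrix
#'
#' Components are maximal sets of `TRUE` pixels mutually reachable through
#' the chosen pixel adjacency (4-neighbour: edge-sharing; 8-neighbour: edge-
#' or corner-sharing). Labelling is performed by building the pixel adjacency
#' graph and extracting its connected components.
#'
#' @param binary Logical (or 0/1) matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of the same shape: 0 for background, components
#'   numbered 1..k (in order of first pixel appearance, column-major).
#' @export
label_components <- function(binary, connectivity = 8) {
  if (!is.matrix(binary)) stop("'binary' must be a matrix")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("'connectivity' must be 4 or 8")
  fg <- which(binary != 0)
  out <- matrix(0L, nrow(binary), ncol(binary))
  if (length(fg) == 0) return(out)

  nr <- nrow(binary)
  nc <- ncol(binary)
  node <- integer(nr * nc)       # linear pixel index -> graph vertex id
  node[fg] <- seq_along(fg)
  row_i <- ((fg - 1L) %% nr) + 1L
  col_i <- ((fg - 1L) %/% nr) + 1L

  offsets <- list(c(1L, 0L), c(0L, 1L))                 # down, right
  if (connectivity == 8L) {
    offsets <- c(offsets, list(c(1L, 1L), c(-1L, 1L)))  # both diagonals
  }
  edge_from <- integer(0)
  edge_to <- integer(0)
  for (off in offsets) {
    r2 <- row_i + off[1]
    c2 <- col_i + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- node[nb] > 0L
    edge_from <- c(edge_from, node[fg[ok]][hit])
    edge_to <- c(edge_to, node[nb][hit])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edge_from) > 0) {
    g <- igraph::add_edges(g, rbind(edge_from, edge_to))
  }
  memb <- igraph::components(g)$membership
  # renumber in order of first (column-major) appearance
  first_seen <- match(unique(memb), memb)
  renum <- integer(max(memb))
  renum[memb[sort(first_seen)]] <- seq_along(first_seen)
  out[fg] <- renum[memb]
  out
}

#' Sizes of labelled components
#'
#' @param labelled Integer matrix as returned by [label_components()].
#' @return Integer vector; element k is the pixel count of component k.
#' @export
component_sizes <- function(labelled) {
  k <- max(labelled)
  if (k == 0L) return(integer(0))
  tabulate(labelled[labelled > 0L], nbins = k)
}

#' Connected-component filtering of a predicted mask
#'
#' For each non-background class independently, connected components are
#' identified and their pixel counts compared against the largest component
#' of that class. Components whose size is at least
#' `threshold_fraction * max(size)` are retained; all other pixels of that
#' class are reset to background. This removes spurious islands while always
#' preserving the largest component (and any component tied with it), and is
#' idempotent.
#'
#' @param mask A [label_mask()].
#' @param threshold_fraction Retention threshold relative to the largest
#'   component, in `(0, 1]`. Default 0.6: components at least 60% the size of
#'   the largest are kept ("at least", so a component exactly at 60% stays).
#' @param connectivity Pixel adjacency, 4 or 8 (default 8).
#' @return A filtered [label_mask()].
#' @export
filter_components <- function(mask, threshold_fraction = 0.6,
                              connectivity = 8) {
  stopifnot(inherits(mask, "label_mask"))
  if (!is.numeric(threshold_fraction) || length(threshold_fraction) != 1 ||
      threshold_fraction <= 0 || threshold_fraction > 1) {
    stop("'threshold_fraction' must be a single number in (0, 1]")
  }
  lab <- mask$labels
  out <- lab
  for (cls in tmj_classes()) {
    comp <- label_components(lab == cls, connectivity = connectivity)
    sizes <- component_sizes(comp)
    if (length(sizes) == 0) next
    keep <- which(sizes >= threshold_fraction * max(sizes))
    drop <- comp > 0L & !(comp %in% keep)
    out[drop] <- 0L
  }
  label_mask(out, spacing_mm = mask$spacing_mm, id = mask$id)
}
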