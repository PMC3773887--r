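# Run-based connected-component labelling with union-find.
# Supports both 4- and 8-connectivity (needed because downstream object
# definition is configurable); operates on row runs so cost scales with
# the number of runs, not mask size.

#' Label connected components of a binary mask
#'
#' @param mask logical matrix.
#' @param connectivity 4 (edge neighbours) or 8 (edge + diagonal).
#' @return integer matrix of the same dimension; background 0, components
#'   labelled 1..n in order of first appearance (row-major).
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  if (!any(mask)) return(lab)

  # runs per row
  run_row <- integer(0); run_s <- integer(0); run_e <- integer(0)
  for (r in seq_len(H)) {
    v <- mask[r, ]
    if (!any(v)) next
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    if (any(keep)) {
      run_row <- c(run_row, rep.int(r, sum(keep)))
      run_s <- c(run_s, starts[keep])
      run_e <- c(run_e, ends[keep])
    }
  }
  n <- length(run_row)
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  # diagonal touch widens the overlap window by one column
  slack <- if (connectivity == 8L) 1L else 0L
  row_of <- split(seq_len(n), run_row)
  rows_present <- as.integer(names(row_of))
  for (k in seq_along(rows_present)) {
    r <- rows_present[k]
    if (k == 1L || rows_present[k - 1L] != r - 1L) next
    cur <- row_of[[k]]; prev <- row_of[[k - 1L]]
    for (i in cur) {
      for (j in prev) {
        if (run_s[i] <= run_e[j] + slack && run_e[i] >= run_s[j] - slack) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- match(roots, unique(roots))
  for (i in seq_len(n)) lab[run_row[i], run_s[i]:run_e[i]] <- labels[i]
  lab
}
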