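#' Canonical two-chamber MEA60 electrode layout
#'
#' Builds the standard layout used throughout the package: an 8 x 8 grid of
#' 60 electrodes (corners absent) split by a micro-tunnel divider into a CA3
#' chamber (grid rows 1-3, 22 electrodes), a DG chamber (rows 6-8, 22
#' electrodes) and 15 in-tunnel electrodes in 8 tunnels on rows 4-5 (tunnel
#' 8 holds a single electrode).  Electrode ids follow the MEA60
#' column-row convention (e.g. 46 = column 4, row 6).
#'
#' @param n_tunnel_electrodes number of monitored in-tunnel electrodes
#'   (default 15; at most 16, two per tunnel column).
#' @return A data frame of class `mea_layout` with columns `electrode_id`,
#'   `region` (`"DG"`, `"CA3"` or `"TUNNEL"`), `tunnel_index` (1-8 or `NA`),
#'   `grid_row`, `grid_col` and `stimulation_capable`.
#' @examples
#' lay <- mea_layout()
#' table(lay$region)
#' @export
mea_layout <- function(n_tunnel_electrodes = 15) {
  stopifnot(n_tunnel_electrodes >= 8, n_tunnel_electrodes <= 16)
  grid <- expand.grid(grid_col = 1:8, grid_row = 1:8)
  corners <- (grid$grid_col %in% c(1, 8)) & (grid$grid_row %in% c(1, 8))
  grid <- grid[!corners, ]
  grid$electrode_id <- 10L * grid$grid_col + grid$grid_row
  grid$region <- ifelse(grid$grid_row <= 3, "CA3",
                        ifelse(grid$grid_row >= 6, "DG", "TUNNEL"))
  grid$tunnel_index <- ifelse(grid$region == "TUNNEL", grid$grid_col, NA_integer_)

  # drop unmonitored tunnel positions from the highest-index tunnels first,
  # lower row first, so the default leaves tunnel 8 with a single electrode
  tun <- which(grid$region == "TUNNEL")
  drop_n <- 16L - as.integer(n_tunnel_electrodes)
  if (drop_n > 0) {
    ord <- tun[order(-grid$tunnel_index[tun], -grid$grid_row[tun])]
    grid <- grid[-match(ord[seq_len(drop_n)], seq_len(nrow(grid))), ]
  }
  grid$stimulation_capable <- grid$region != "TUNNEL"
  grid <- grid[order(grid$electrode_id),
               c("electrode_id", "region", "tunnel_index",
                 "grid_row", "grid_col", "stimulation_capable")]
  rownames(grid) <- NULL
  class(grid) <- c("mea_layout", "data.frame")
  grid
}

#' Validate an electrode layout
#'
#' Checks every structural invariant of a two-chamber layout and reports all
#' violations at once: 22 DG and 22 CA3 electrodes, at most 16 tunnel
#' electrodes grouped into at most 8 tunnels of 1-2 members, unique
#' electrode ids, and grid positions on the 8 x 8 grid.
#'
#' @param layout a layout data frame as returned by [mea_layout()].
#' @return Character vector of human-readable violations; `character(0)` if
#'   and only if the layout is valid.
#' @examples
#' validate_layout(mea_layout())   # character(0)
#' @export
validate_layout <- function(layout) {
  bad <- character(0)
  need <- c("electrode_id", "region", "tunnel_index", "grid_row", "grid_col")
  miss <- setdiff(need, names(layout))
  if (length(miss))
    return(paste0("missing columns: ", paste(miss, collapse = ", ")))
  if (anyDuplicated(layout$electrode_id))
    bad <- c(bad, "electrode ids are not unique")
  for (reg in c("DG", "CA3")) {
    n <- sum(layout$region == reg)
    if (n != 22)
      bad <- c(bad, sprintf("expected 22 %s electrodes, found %d", reg, n))
  }
  tun <- layout[layout$region == "TUNNEL", ]
  if (nrow(tun) > 16)
    bad <- c(bad, sprintf("%d tunnel electrodes exceed the maximum of 16", nrow(tun)))
  if (nrow(tun)) {
    if (any(is.na(tun$tunnel_index)))
      bad <- c(bad, "tunnel electrodes with missing tunnel_index")
    sz <- table(tun$tunnel_index)
    if (length(sz) > 8)
      bad <- c(bad, sprintf("%d tunnels exceed the maximum of 8", length(sz)))
    if (any(sz > 2))
      bad <- c(bad, "a tunnel holds more than 2 electrodes")
  }
  if (any(!is.na(layout$tunnel_index) & layout$region != "TUNNEL"))
    bad <- c(bad, "non-tunnel electrode carries a tunnel_index")
  if (any(layout$grid_row < 1 | layout$grid_row > 8 |
          layout$grid_col < 1 | layout$grid_col > 8))
    bad <- c(bad, "grid positions outside the 8 x 8 grid")
  bad
}

#' @export
print.mea_layout <- function(x, ...) {
  cat(sprintf("<mea_layout> %d electrodes: %d DG, %d CA3, %d tunnel (%d tunnels)\n",
              nrow(x), sum(x$region == "DG"), sum(x$region == "CA3"),
              sum(x$region == "TUNNEL"),
              length(unique(stats::na.omit(x$tunnel_index)))))
  v <- validate_layout(x)
  if (length(v)) cat("invalid:", paste(v, collapse = "; "), "\n")
  invisible(x)
}

#' @rdname mea_layout
#' @param layout a layout data frame.
#' @param region `"DG"`, `"CA3"` or `"TUNNEL"`.
#' @return `region_electrodes()`: the region's electrode ids in id order.
#' @export
region_electrodes <- function(layout, region) {
  layout$electrode_id[layout$region == region]
}
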