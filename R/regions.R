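#' Recognised region labels
#'
#' The closed set of land-use categories a raster cell can carry. Each label
#' maps to one column of a region parameter table (area support, wind,
#' diffusion, insecticide kill rates).
#'
#' @return Character vector of admissible labels.
#' @export
region_labels <- function() {
  c("block", "street", "park", "beach", "treated_street")
}

#' Region raster
#'
#' Wraps a per-cell label matrix into a validated `region_map`. Every cell
#' must carry exactly one label from [region_labels()]; unknown labels are
#' rejected.
#'
#' @param labels Character matrix (`nx x ny`) of region labels.
#' @param grid The [fv_grid()] the raster lives on.
#' @param provenance Free-text description of where the layout comes from.
#' @return An object of class `region_map`: list with `labels`, `grid`,
#'   `provenance`.
#' @export
region_map <- function(labels, grid, provenance = "") {
  stopifnot(inherits(grid, "fv_grid"))
  check_field(labels, grid, "labels")
  if (anyNA(labels)) stop("every cell must have a label", call. = FALSE)
  bad <- setdiff(unique(as.vector(labels)), region_labels())
  if (length(bad) > 0) {
    stop("unknown region label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(labels = labels, grid = grid, provenance = provenance),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<region_map> %d x %d cells; labels: %s\n",
              x$grid$nx, x$grid$ny,
              paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", ")))
  if (nzchar(x$provenance)) cat(" provenance:", x$provenance, "\n")
  invisible(x)
}

#' Rasterize a rectangle layout onto a grid
#'
#' Paints axis-aligned rectangles onto the grid by cell-centre sampling: each
#' cell takes the label of the *last* rectangle in the list covering its
#' centre, and uncovered cells take the background label. Cell-centre
#' sampling (rather than area-weighted mixing) matches the piecewise-constant
#' coefficient fields of the finite-volume scheme.
#'
#' @param grid An [fv_grid()].
#' @param rectangles A data frame / tibble with columns `label`, `x0`, `y0`,
#'   `x1`, `y1` (metres, corners with `x0 < x1`, `y0 < y1`). May have zero
#'   rows.
#' @param background Label for uncovered cells (default `"street"`).
#' @param provenance Free-text layout description.
#' @return A [region_map()].
#' @examples
#' g <- fv_grid(4, 4, 200, 200)
#' rasterize_blocks(g, tibble::tibble(label = "block",
#'                                    x0 = 0, y0 = 0, x1 = 100, y1 = 100))
#' @export
rasterize_blocks <- function(grid, rectangles = NULL, background = "street",
                             provenance = "") {
  stopifnot(inherits(grid, "fv_grid"))
  if (!background %in% region_labels()) {
    stop("unknown background label: ", background, call. = FALSE)
  }
  labels <- const_field(background, grid)
  if (!is.null(rectangles) && nrow(rectangles) > 0) {
    need <- c("label", "x0", "y0", "x1", "y1")
    if (!all(need %in% names(rectangles))) {
      stop("rectangles must have columns ", paste(need, collapse = ", "), call. = FALSE)
    }
    xc <- (seq_len(grid$nx) - 0.5) * grid$dx
    yc <- (seq_len(grid$ny) - 0.5) * grid$dy
    for (k in seq_len(nrow(rectangles))) {
      r <- rectangles[k, ]
      if (!r$label %in% region_labels()) {
        stop("unknown region label: ", r$label, call. = FALSE)
      }
      if (r$x1 <= r$x0 || r$y1 <= r$y0) {
        stop(sprintf("empty rectangle %d (x1 <= x0 or y1 <= y0)", k), call. = FALSE)
      }
      if (r$x0 < 0 || r$y0 < 0 || r$x1 > grid$Lx || r$y1 > grid$Ly) {
        stop(sprintf("rectangle %d lies outside the domain", k), call. = FALSE)
      }
      ii <- which(xc >= r$x0 & xc < r$x1)
      jj <- which(yc >= r$y0 & yc < r$y1)
      if (length(ii) && length(jj)) labels[ii, jj] <- r$label
    }
  }
  region_map(labels, grid, provenance)
}

#' Region areas
#'
#' @param regions A [region_map()].
#' @return Tibble with columns `label`, `cells`, `area_m2`.
#' @export
region_areas <- function(regions) {
  stopifnot(inherits(regions, "region_map"))
  tab <- table(regions$labels)
  tibble::tibble(
    label = names(tab),
    cells = as.integer(tab),
    area_m2 = as.integer(tab) * regions$grid$dx * regions$grid$dy
  )
}

#' Read / write a region raster as a plain-text label grid
#'
#' The on-disk format is a headerless CSV of integer codes, row-major with
#' row 1 = the y = 0 row of the domain, plus a sidecar legend file
#' (`<path>.legend`) mapping codes to label names, one `code,label` pair per
#' line.
#'
#' @param regions A [region_map()].
#' @param path File path for the CSV grid.
#' @return `write_region_csv()` returns `path` invisibly; `read_region_csv()`
#'   returns a [region_map()].
#' @export
write_region_csv <- function(regions, path) {
  stopifnot(inherits(regions, "region_map"))
  labs <- sort(unique(as.vector(regions$labels)))
  codes <- matrix(match(regions$labels, labs), nrow = regions$grid$nx)
  # rows of the file are y-rows: transpose so file row r = y index r
  utils::write.table(t(codes), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("%d,%s", seq_along(labs), labs), paste0(path, ".legend"))
  invisible(path)
}

#' @rdname write_region_csv
#' @param grid Grid the raster is read onto; the file dimensions must match.
#' @param provenance Free-text description attached to the result.
#' @export
read_region_csv <- function(path, grid, provenance = paste("read from", path)) {
  codes <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  leg <- utils::read.table(paste0(path, ".legend"), sep = ",", header = FALSE,
                           col.names = c("code", "label"),
                           colClasses = c("integer", "character"))
  if (nrow(codes) != grid$ny || ncol(codes) != grid$nx) {
    stop("label grid dimensions do not match the grid", call. = FALSE)
  }
  labels <- matrix(leg$label[match(t(codes), leg$code)], nrow = grid$nx)
  region_map(labels, grid, provenance)
}
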