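#' Cell-centred rectangular grid
#'
#' Builds the uniform cell-centred mesh over the domain
#' \eqn{\Omega = [0, Lx] \times [0, Ly]}. Cell `(i, j)` (1-based) is centred at
#' `((i - 1/2) dx, (j - 1/2) dy)`; faces sit at integer multiples of the cell
#' sizes. Fields defined on the grid are `nx x ny` matrices whose rows index
#' x and columns index y.
#'
#' @param nx,ny Number of cells in x and y (each at least 2).
#' @param Lx,Ly Domain extent in metres.
#' @return An object of class `fv_grid`: a list with `nx`, `ny`, `Lx`, `Ly`,
#'   `dx`, `dy`.
#' @examples
#' g <- fv_grid(100, 100, 200, 200)
#' g$dx
#' @export
fv_grid <- function(nx, ny, Lx, Ly) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 2L || ny < 2L) stop("grid needs at least 2 cells per direction", call. = FALSE)
  if (Lx <= 0 || Ly <= 0) stop("domain extents must be positive", call. = FALSE)
  structure(
    list(nx = nx, ny = ny, Lx = Lx, Ly = Ly, dx = Lx / nx, dy = Ly / ny),
    class = "fv_grid"
  )
}

#' @export
print.fv_grid <- function(x, ...) {
  cat(sprintf("<fv_grid> %d x %d cells over %g x %g m (dx = %g m, dy = %g m)\n",
              x$nx, x$ny, x$Lx, x$Ly, x$dx, x$dy))
  invisible(x)
}

#' Cell-centre coordinates
#'
#' @param grid An [fv_grid()].
#' @return A tibble with one row per cell: integer indices `i`, `j` and
#'   centre coordinates `x`, `y` in metres (column-major cell order, matching
#'   `as.vector()` on a field matrix).
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "fv_grid"))
  tibble::tibble(
    i = rep(seq_len(grid$nx), times = grid$ny),
    j = rep(seq_len(grid$ny), each = grid$nx),
    x = (rep(seq_len(grid$nx), times = grid$ny) - 0.5) * grid$dx,
    y = (rep(seq_len(grid$ny), each = grid$nx) - 0.5) * grid$dy
  )
}

check_field <- function(field, grid, what = "field") {
  if (!is.matrix(field) || nrow(field) != grid$nx || ncol(field) != grid$ny) {
    stop(sprintf("%s must be a %d x %d matrix matching the grid",
                 what, grid$nx, grid$ny), call. = FALSE)
  }
  invisible(field)
}

const_field <- function(value, grid) {
  matrix(value, nrow = grid$nx, ncol = grid$ny)
}
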