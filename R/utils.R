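# Internal helpers shared across modules.

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Convert grid (row, col) pairs to serialized cell ids
#'
#' Cells are addressed by 0-based (row, col) integer pairs and serialized
#' row-major: `cell_id = row * n_cols + col`.
#'
#' @param row,col 0-based integer indices.
#' @param n_cols number of grid columns.
#' @return Integer cell ids.
#' @seealso [cell_to_rowcol()]
#' @export
#' @examples
#' rowcol_to_cell(0, 0, 10)  # 0
#' rowcol_to_cell(1, 2, 10)  # 12
rowcol_to_cell <- function(row, col, n_cols) {
  stopifnot(all(row >= 0), all(col >= 0), all(col < n_cols))
  as.integer(row * n_cols + col)
}

#' Convert serialized cell ids back to (row, col)
#'
#' @param cell_id integer ids from [rowcol_to_cell()].
#' @param n_cols number of grid columns.
#' @return data.frame with columns `row`, `col` (0-based).
#' @export
cell_to_rowcol <- function(cell_id, n_cols) {
  data.frame(row = cell_id %/% n_cols, col = cell_id %% n_cols)
}

bioclim_vars <- c("bio01", "bio05", "bio06", "bio12", "bio13", "bio14")

key_organs <- c("brain", "heart", "lungs", "liver", "spleen", "kidneys")

stop_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}
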