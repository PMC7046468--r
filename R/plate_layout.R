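## 384-well plate layouts.

#' Construct a 384-well plate layout
#'
#' The default layout mirrors the screening arrangement this package models:
#' 16 DMSO vehicle wells (column 24), 8 pristimerin motility positive
#' controls and 8 A23187 acrosome-reaction positive controls (column 23),
#' and compound wells in columns 1-22.
#'
#' @param plate_id Plate identifier.
#' @param n_rows,n_cols Plate geometry (16 x 24 for 384-well).
#' @param dmso_cols,pristimerin_rows,a23187_rows Control placement: DMSO
#'   fills `dmso_cols`; column `control_col` is split between pristimerin
#'   and A23187 rows.
#' @param control_col Column holding the positive controls.
#'
#' @return A `data.table` of class `plate_layout` with columns `plate_id`,
#'   `well`, `row_idx`, `col_idx`, `role`
#'   (`compound|dmso|pristimerin|a23187|empty`) and `compound_id`.
#' @export
plate_layout <- function(plate_id = "plate01", n_rows = 16L, n_cols = 24L,
                         dmso_cols = 24L,
                         pristimerin_rows = 1:8, a23187_rows = 9:16,
                         control_col = 23L) {
  stopifnot(n_rows >= 1L, n_cols >= 1L, n_rows <= 26L)
  grid <- CJ(row_idx = seq_len(n_rows), col_idx = seq_len(n_cols))
  grid[, well := sprintf("%s%02d", LETTERS[row_idx], col_idx)]
  grid[, role := "compound"]
  grid[col_idx %in% dmso_cols, role := "dmso"]
  grid[col_idx == control_col & row_idx %in% pristimerin_rows, role := "pristimerin"]
  grid[col_idx == control_col & row_idx %in% a23187_rows, role := "a23187"]
  grid[, compound_id := NA_character_]
  grid[role == "compound",
       compound_id := sprintf("CPD%04d", seq_len(sum(grid$role == "compound")))]
  grid[, plate_id := plate_id]
  setcolorder(grid, c("plate_id", "well", "row_idx", "col_idx", "role", "compound_id"))
  setattr(grid, "class", c("plate_layout", class(grid)))
  grid[]
}

#' @rdname plate_layout
#' @param layout Object to validate.
#' @export
validate_plate_layout <- function(layout) {
  stopifnot(is.data.frame(layout))
  need <- c("well", "row_idx", "col_idx", "role")
  if (!all(need %in% names(layout))) {
    stop("plate layout needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(layout$well)) stop("duplicate wells in plate layout")
  ok <- c("compound", "dmso", "pristimerin", "a23187", "empty")
  if (!all(layout$role %in% ok)) {
    stop("unknown roles: ", paste(setdiff(unique(layout$role), ok), collapse = ", "))
  }
  if (!any(layout$role == "dmso")) stop("layout has no DMSO well")
  invisible(layout)
}
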