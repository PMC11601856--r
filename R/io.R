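#' Write and read gridded cubes as long-format CSV
#'
#' Cubes (cell-by-day matrices) are persisted as plain CSV with columns
#' `cell_id`, `day_index`, `value`, one file per variable.
#'
#' @param mat cell-by-day matrix aligned to `domain` rows.
#' @param domain grid domain.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cube_csv <- function(mat, domain, path) {
  df <- data.frame(
    cell_id = rep(domain$cell_id, times = ncol(mat)),
    day_index = rep(seq_len(ncol(mat)), each = nrow(mat)),
    value = as.vector(mat)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cube_csv
#' @return `read_cube_csv` returns the cell-by-day matrix.
#' @export
read_cube_csv <- function(path, domain) {
  df <- utils::read.csv(path)
  n_days <- max(df$day_index)
  m <- matrix(NA_real_, nrow(domain), n_days)
  m[cbind(match(df$cell_id, domain$cell_id), df$day_index)] <- df$value
  m
}

#' Load a run configuration
#'
#' Reads a YAML configuration (or accepts a list) and merges it over
#' [default_config()], so partial files override only the keys they
#' name.
#'
#' @param x YAML file path or a (possibly partial) config list.
#' @return complete configuration list.
#' @export
load_config <- function(x = list()) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  merge_cfg <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        merge_cfg(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  merge_cfg(default_config(), cfg)
}
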