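#' Read sample metadata
#'
#' Expects a TSV/CSV (delimiter inferred from extension) with a `sample_id`
#' column and optional `input_mass_pg`, `group` and `is_control` columns.
#' Missing `input_mass_pg` cells — or a missing column — leave the mass
#' unknown for those samples, in which case downstream mass estimation must
#' run in spike-in inference mode.
#'
#' @param path Path to the metadata file.
#' @return data.frame with columns `sample_id`, `input_mass_pg` (numeric, NA
#'   when unknown), `group` (character, NA when absent) and `is_control`
#'   (logical, NA when absent).
#' @export
load_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("metadata must contain a 'sample_id' column", call. = FALSE)
  }
  id <- as.character(df$sample_id)
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    stop("duplicate sample_id in metadata: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  mass <- if ("input_mass_pg" %in% names(df)) {
    suppressWarnings(as.numeric(df$input_mass_pg))
  } else {
    rep(NA_real_, length(id))
  }
  known <- !is.na(mass)
  if (any(mass[known] <= 0)) {
    stop("non-positive input_mass_pg for sample(s): ",
         paste(id[known][mass[known] <= 0], collapse = ", "), call. = FALSE)
  }
  data.frame(
    sample_id = id,
    input_mass_pg = mass,
    group = if ("group" %in% names(df)) as.character(df$group) else NA_character_,
    is_control = if ("is_control" %in% names(df)) as.logical(df$is_control) else NA,
    stringsAsFactors = FALSE
  )
}
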