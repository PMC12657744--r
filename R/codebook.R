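#' Item codebook
#'
#' Describes the items of a dichotomous scale: identifier, free-text label,
#' and whether the item is positively worded (reverse-keyed) so that a "yes"
#' points away from the construct and must be flipped before modeling.
#'
#' @param item_id character vector of unique short item identifiers.
#' @param label character vector of item labels (defaults to `item_id`).
#' @param reverse_keyed logical vector flagging reverse-keyed items.
#' @return An object of class `item_codebook` (a data frame).
#' @examples
#' item_codebook(c("a", "b"), reverse_keyed = c(FALSE, TRUE))
#' @export
item_codebook <- function(item_id, label = item_id,
                          reverse_keyed = rep(FALSE, length(item_id))) {
  item_id <- as.character(item_id)
  if (length(item_id) < 2L) stop("a codebook needs at least 2 items")
  if (anyDuplicated(item_id)) stop("item ids must be unique")
  if (length(label) != length(item_id) ||
      length(reverse_keyed) != length(item_id))
    stop("label and reverse_keyed must match item_id in length")
  cb <- data.frame(item_id = item_id, label = as.character(label),
                   reverse_keyed = as.logical(reverse_keyed),
                   stringsAsFactors = FALSE)
  class(cb) <- c("item_codebook", "data.frame")
  cb
}

#' Default CES-D-8 codebook
#'
#' The eight dichotomous CES-D items (five depressed-affect, three somatic);
#' "was happy" and "enjoyed life" are positively worded and flagged
#' reverse-keyed.
#'
#' @return An `item_codebook` with 8 items.
#' @export
cesd8_codebook <- function() {
  item_codebook(
    item_id = c("depressed", "effort", "sleep", "happy",
                "lonely", "enjoy", "sad", "getgoing"),
    label = c("felt depressed", "everything was an effort",
              "sleep was restless", "was happy", "felt lonely",
              "enjoyed life", "felt sad", "could not get going"),
    reverse_keyed = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  )
}

#' Read / write a codebook as YAML or JSON
#'
#' @param path file path; format inferred from the extension
#'   (`.yaml`/`.yml` or `.json`).
#' @return `read_codebook` returns an `item_codebook`; `write_codebook`
#'   returns `path` invisibly.
#' @export
read_codebook <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unknown codebook format: ", ext))
  if (is.data.frame(raw)) {
    item_codebook(raw$item_id, raw$label, raw$reverse_keyed)
  } else {
    item_codebook(vapply(raw, `[[`, "", "item_id"),
                  vapply(raw, `[[`, "", "label"),
                  vapply(raw, `[[`, TRUE, "reverse_keyed"))
  }
}

#' @rdname read_codebook
#' @param codebook an `item_codebook`.
#' @export
write_codebook <- function(codebook, path) {
  ext <- tolower(tools::file_ext(path))
  rows <- lapply(seq_len(nrow(codebook)), function(i)
    list(item_id = codebook$item_id[i], label = codebook$label[i],
         reverse_keyed = codebook$reverse_keyed[i]))
  switch(ext,
    yaml = , yml = yaml::write_yaml(rows, path),
    json = jsonlite::write_json(rows, path, auto_unbox = TRUE),
    stop("unknown codebook format: ", ext))
  invisible(path)
}
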