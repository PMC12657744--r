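#' Panel dataset of binary item responses
#'
#' Container for N persons responding to a set of dichotomous items over
#' ordered waves, with optional per-person auxiliary covariates. Responses
#' are stored as an `N x items x waves` array with values 0, 1 or `NA`.
#'
#' @param responses numeric array `N x items x waves`, values in {0, 1, NA}.
#' @param codebook an [item_codebook()] describing the items (second
#'   dimension of `responses`).
#' @param persons person identifiers (unique); default `p1..pN`.
#' @param waves ordered wave labels; default `w1..wW`.
#' @param aux optional data frame of per-person auxiliary covariates
#'   (N rows, numeric or factor columns).
#' @return An object of class `clpn_panel`.
#' @export
panel_dataset <- function(responses, codebook,
                          persons = NULL, waves = NULL, aux = NULL) {
  if (length(dim(responses)) != 3L)
    stop("responses must be an N x items x waves array")
  n <- dim(responses)[1L]
  n_items <- dim(responses)[2L]
  n_waves <- dim(responses)[3L]
  if (n_items != nrow(codebook))
    stop("responses item dimension does not match codebook")
  persons <- as.character(persons %||% paste0("p", seq_len(n)))
  waves <- as.character(waves %||% paste0("w", seq_len(n_waves)))
  if (anyDuplicated(persons)) stop("person ids must be unique")
  if (anyDuplicated(waves)) stop("wave labels must be unique")
  bad <- responses[!is.na(responses) & responses != 0 & responses != 1]
  if (length(bad))
    stop("responses must be coded strictly {0,1}; found value(s): ",
         paste(utils::head(unique(bad), 3), collapse = ", "))
  if (!is.null(aux)) {
    aux <- as.data.frame(aux)
    if (nrow(aux) != n) stop("aux must have one row per person")
  }
  storage.mode(responses) <- "double"
  dimnames(responses) <- list(persons, codebook$item_id, waves)
  structure(list(persons = persons, waves = waves,
                 items = codebook$item_id, responses = responses,
                 aux = aux, codebook = codebook),
            class = "clpn_panel")
}

#' @export
print.clpn_panel <- function(x, ...) {
  n_miss <- sum(is.na(x$responses))
  cat(sprintf(
    "clpn_panel: %d persons x %d items x %d waves (%d missing cells, %.1f%%)\n",
    length(x$persons), length(x$items), length(x$waves), n_miss,
    100 * n_miss / length(x$responses)))
  cat("items:", paste(x$items, collapse = ", "), "\n")
  cat("waves:", paste(x$waves, collapse = ", "), "\n")
  if (!is.null(x$aux))
    cat("aux:", paste(names(x$aux), collapse = ", "), "\n")
  invisible(x)
}

#' Extract one wave of a panel as an items matrix
#'
#' @param panel a `clpn_panel`.
#' @param wave a wave label.
#' @return Numeric matrix `N x items`.
#' @export
wave_matrix <- function(panel, wave) {
  if (!wave %in% panel$waves) stop("unknown wave: ", wave)
  panel$responses[, , wave, drop = TRUE]
}

#' Per-person sum scores for one wave
#'
#' Sum of item responses at one wave; `NA` if any item is missing for that
#' person-wave.
#'
#' @inheritParams wave_matrix
#' @return Numeric vector of length N.
#' @export
sum_scores <- function(panel, wave) {
  rowSums(wave_matrix(panel, wave))
}

# Subset persons of a panel (internal).
subset_persons <- function(panel, idx, relabel = FALSE) {
  resp <- panel$responses[idx, , , drop = FALSE]
  persons <- panel$persons[idx]
  if (relabel || anyDuplicated(persons))
    persons <- paste0("p", seq_along(idx))
  aux <- if (!is.null(panel$aux)) panel$aux[idx, , drop = FALSE] else NULL
  if (!is.null(aux)) rownames(aux) <- NULL
  panel_dataset(resp, panel$codebook, persons = persons,
                waves = panel$waves, aux = aux)
}
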