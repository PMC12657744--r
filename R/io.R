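#' Read a panel dataset from CSV
#'
#' Two layouts are supported. `long` (canonical on disk): columns `person`,
#' `wave`, `item`, `value`, plus optional auxiliary columns constant within
#' person. `wide`: one row per person, response columns named
#' `<item>_<wave>`; any other column except `person` is treated as an
#' auxiliary covariate.
#'
#' Values must be coded strictly 0/1; tokens listed in `missing_tokens`
#' (and empty cells) become missing. Any other numeric value is an error —
#' Likert-style inputs are refused rather than silently coerced. Other
#' unparseable strings become missing with a logged count.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param layout `"long"` or `"wide"`.
#' @param codebook an [item_codebook()]; response items must be a subset of
#'   its ids.
#' @param missing_tokens character tokens to read as missing.
#' @param waves optional wave ordering; defaults to order of appearance
#'   (long) or column order (wide).
#' @return A [panel_dataset()].
#' @export
read_panel <- function(path, layout = c("long", "wide"), codebook,
                       missing_tokens = c("", "NA", "na", "."),
                       waves = NULL) {
  layout <- match.arg(layout)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (layout == "long") {
    need <- c("person", "wave", "item", "value")
    if (!all(need %in% names(df)))
      stop("long layout needs columns: ", paste(need, collapse = ", "))
    unknown <- setdiff(unique(df$item), codebook$item_id)
    if (length(unknown))
      stop("unknown item id(s): ", paste(unknown, collapse = ", "))
    key <- paste(df$person, df$wave, df$item, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate person-wave-item cells in ", path)
    persons <- unique(df$person)
    waves <- waves %||% unique(df$wave)
    items <- codebook$item_id
    val <- parse_binary(df$value, missing_tokens)
    resp <- array(NA_real_, dim = c(length(persons), length(items),
                                    length(waves)))
    i_p <- match(df$person, persons)
    i_i <- match(df$item, items)
    i_w <- match(df$wave, waves)
    resp[cbind(i_p, i_i, i_w)] <- val
    aux_cols <- setdiff(names(df), need)
    aux <- NULL
    if (length(aux_cols)) {
      first <- !duplicated(df$person)
      aux <- df[first, aux_cols, drop = FALSE][order(match(df$person[first],
                                                           persons)), ,
                                               drop = FALSE]
      aux[] <- lapply(aux, utils::type.convert, as.is = TRUE)
      rownames(aux) <- NULL
    }
    panel_dataset(resp, codebook, persons = persons, waves = waves, aux = aux)
  } else {
    if (!"person" %in% names(df)) stop("wide layout needs a person column")
    if (anyDuplicated(df$person)) stop("duplicate person rows in ", path)
    rx <- paste0("^(", paste(codebook$item_id, collapse = "|"), ")_(.+)$")
    resp_cols <- grep(rx, names(df), value = TRUE)
    if (!length(resp_cols)) stop("no <item>_<wave> response columns found")
    item_of <- sub(rx, "\\1", resp_cols)
    wave_of <- sub(rx, "\\2", resp_cols)
    waves <- waves %||% unique(wave_of)
    items <- codebook$item_id
    resp <- array(NA_real_, dim = c(nrow(df), length(items), length(waves)))
    for (k in seq_along(resp_cols)) {
      resp[, match(item_of[k], items), match(wave_of[k], waves)] <-
        parse_binary(df[[resp_cols[k]]], missing_tokens)
    }
    aux_cols <- setdiff(names(df), c("person", resp_cols))
    aux <- NULL
    if (length(aux_cols)) {
      aux <- df[, aux_cols, drop = FALSE]
      aux[] <- lapply(aux, utils::type.convert, as.is = TRUE)
      rownames(aux) <- NULL
    }
    panel_dataset(resp, codebook, persons = df$person, waves = waves,
                  aux = aux)
  }
}

# Parse a character vector into {0, 1, NA}; strict about other numerics.
parse_binary <- function(x, missing_tokens) {
  x <- trimws(x)
  out <- rep(NA_real_, length(x))
  is_miss <- is.na(x) | x %in% missing_tokens
  num <- suppressWarnings(as.numeric(x[!is_miss]))
  bad_numeric <- !is.na(num) & num != 0 & num != 1
  if (any(bad_numeric))
    stop("values must be coded strictly {0,1}; found: ",
         paste(utils::head(unique(num[bad_numeric]), 3), collapse = ", "))
  n_unparseable <- sum(is.na(num))
  if (n_unparseable > 0)
    message(n_unparseable, " unparseable value(s) treated as missing")
  out[!is_miss] <- num
  out
}

#' Write a panel dataset to CSV (long layout)
#'
#' Long layout is the canonical on-disk form: one row per person-wave-item,
#' with auxiliary covariates repeated on each row. Missing responses are
#' written as empty cells.
#'
#' @param panel a [panel_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  n <- length(panel$persons); p <- length(panel$items)
  w <- length(panel$waves)
  df <- data.frame(
    person = rep(panel$persons, times = p * w),
    wave = rep(panel$waves, each = n * p),
    item = rep(rep(panel$items, each = n), times = w),
    value = as.vector(panel$responses),
    stringsAsFactors = FALSE)
  if (!is.null(panel$aux))
    df <- cbind(df, panel$aux[rep(seq_len(n), times = p * w), , drop = FALSE])
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Recode reverse-keyed items toward the construct
#'
#' Flips 0 and 1 on every item flagged `reverse_keyed` in the codebook and
#' clears the flags, so applying the operation twice equals applying it
#' once. Missing stays missing.
#'
#' @param panel a [panel_dataset()].
#' @return The recoded panel.
#' @export
recode_reverse <- function(panel) {
  flip <- panel$codebook$reverse_keyed
  if (any(flip))
    panel$responses[, flip, ] <- 1 - panel$responses[, flip, , drop = FALSE]
  panel$codebook$reverse_keyed[] <- FALSE
  panel
}

#' Export a fitted network to an edge list CSV or GraphML
#'
#' The edge list holds one row per non-zero entry of the coefficient matrix
#' with columns `source`, `target`, `log_odds`, `odds_ratio`,
#' `is_autoregressive`. GraphML output carries the same edge attributes plus
#' per-node intercepts, so it round-trips the full network.
#'
#' @param net a `clpn_network` (see [fit_clpn()]).
#' @param path output file path.
#' @param format `"edge_list_csv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("edge_list_csv", "graphml")) {
  format <- match.arg(format)
  B <- net$B
  nz <- which(B != 0, arr.ind = TRUE)
  edges <- data.frame(
    source = net$items[nz[, 1]],
    target = net$items[nz[, 2]],
    log_odds = B[nz],
    odds_ratio = exp(B[nz]),
    is_autoregressive = nz[, 1] == nz[, 2],
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  if (format == "edge_list_csv") {
    utils::write.csv(edges, path, row.names = FALSE)
  } else {
    doc <- xml2::xml_new_root("graphml",
      xmlns = "http://graphml.graphdrawing.org/xmlns")
    keydefs <- list(
      c("d_lo", "edge", "log_odds", "double"),
      c("d_or", "edge", "odds_ratio", "double"),
      c("d_ar", "edge", "is_autoregressive", "boolean"),
      c("d_ic", "node", "intercept", "double"))
    for (k in keydefs)
      xml2::xml_add_child(doc, "key", id = k[1], `for` = k[2],
                          attr.name = k[3], attr.type = k[4])
    g <- xml2::xml_add_child(doc, "graph", id = "clpn",
                             edgedefault = "directed")
    for (i in seq_along(net$items)) {
      nd <- xml2::xml_add_child(g, "node", id = net$items[i])
      d <- xml2::xml_add_child(nd, "data", key = "d_ic")
      xml2::xml_text(d) <- format(net$intercepts[i], digits = 17)
    }
    for (r in seq_len(nrow(edges))) {
      e <- xml2::xml_add_child(g, "edge", source = edges$source[r],
                               target = edges$target[r])
      vals <- c(d_lo = format(edges$log_odds[r], digits = 17),
                d_or = format(edges$odds_ratio[r], digits = 17),
                d_ar = tolower(as.character(edges$is_autoregressive[r])))
      for (k in names(vals)) {
        d <- xml2::xml_add_child(e, "data", key = k)
        xml2::xml_text(d) <- vals[[k]]
      }
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' Import a network from an edge list CSV or GraphML
#'
#' @param path file written by [export_network()].
#' @param format `"edge_list_csv"` or `"graphml"`.
#' @param items node labels; required for CSV (an edge list does not carry
#'   isolated nodes), inferred from the file for GraphML.
#' @return A `clpn_network` (intercepts are `NA` for CSV input).
#' @export
import_network <- function(path, format = c("edge_list_csv", "graphml"),
                           items = NULL) {
  format <- match.arg(format)
  if (format == "edge_list_csv") {
    if (is.null(items)) stop("items must be given for edge-list CSV import")
    edges <- utils::read.csv(path, stringsAsFactors = FALSE)
    B <- matrix(0, length(items), length(items),
                dimnames = list(items, items))
    if (nrow(edges))
      B[cbind(match(edges$source, items), match(edges$target, items))] <-
        edges$log_odds
    intercepts <- stats::setNames(rep(NA_real_, length(items)), items)
  } else {
    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)
    nodes <- xml2::xml_find_all(doc, ".//graph/node")
    items <- xml2::xml_attr(nodes, "id")
    intercepts <- stats::setNames(as.numeric(
      xml2::xml_text(xml2::xml_find_first(nodes, "./data[@key='d_ic']"))),
      items)
    B <- matrix(0, length(items), length(items),
                dimnames = list(items, items))
    for (e in xml2::xml_find_all(doc, ".//graph/edge")) {
      s <- xml2::xml_attr(e, "source"); t <- xml2::xml_attr(e, "target")
      lo <- as.numeric(xml2::xml_text(
        xml2::xml_find_first(e, "./data[@key='d_lo']")))
      B[s, t] <- lo
    }
  }
  new_clpn_network(items = items, B = B, intercepts = intercepts,
                   lambda_used = rep(NA_real_, length(items)),
                   n_fit = NA_integer_, wave_pair = c(NA, NA))
}
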