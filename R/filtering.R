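#' Construct filter parameters
#'
#' Filters are a conjunction of per-field tests: variable range filters
#' (inclusive `min`/`max`, optionally inverted), category key filters
#' (include or exclude a set of labels; exclude is the default mode, matching
#' the typical use of removing `no-hit` or contaminant labels) and named
#' identifier lists applied last.
#'
#' @param variable Named list: field id -> list(min =, max =, invert =).
#' @param category Named list: field id -> list(keys = character,
#'   mode = "include"|"exclude").
#' @param id_lists List of list(ids = character, mode = "include"|"exclude").
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(variable = list(), category = list(),
                          id_lists = list()) {
  for (nm in names(variable)) {
    v <- variable[[nm]]
    if (!is.null(v$min) && !is.null(v$max) && v$min > v$max) {
      stop("filter on '", nm, "': min exceeds max", call. = FALSE)
    }
  }
  for (nm in names(category)) {
    c_ <- category[[nm]]
    if (!length(c_$keys)) stop("filter on '", nm, "': empty key set",
                               call. = FALSE)
    category[[nm]]$mode <- match.arg(c_$mode %||% "exclude",
                                     c("exclude", "include"))
    category[[nm]]$keys <- as.character(c_$keys)
  }
  for (i in seq_along(id_lists)) {
    id_lists[[i]]$mode <- match.arg(id_lists[[i]]$mode %||% "include",
                                    c("include", "exclude"))
  }
  # canonical field order, so parse(encode(p)) is an identity
  if (length(variable)) variable <- variable[order(names(variable))]
  if (length(category)) category <- category[order(names(category))]
  structure(list(variable = variable, category = category,
                 id_lists = id_lists),
            class = "filter_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.filter_params <- function(x, ...) {
  cat("filter_params:", encode_query(x), "\n")
  if (length(x$id_lists)) {
    cat("  +", length(x$id_lists), "identifier list(s)\n")
  }
  invisible(x)
}

#' Compute a per-contig inclusion mask for a set of filters
#'
#' A contig is retained iff it passes every active filter. A variable filter
#' passes when `min <= value <= max` (both bounds inclusive; absent bounds
#' are open), negated under `invert`. A category `include` filter passes when
#' the contig's label is in the key set; `exclude` when it is not. Identifier
#' lists are applied last.
#'
#' @param dataset A `blobdir`.
#' @param params A [filter_params()] object.
#' @return Logical vector over the dataset identifiers.
#' @export
build_mask <- function(dataset, params) {
  stopifnot(inherits(dataset, "blobdir"), inherits(params, "filter_params"))
  n <- length(dataset$identifiers)
  mask <- rep(TRUE, n)
  for (nm in names(params$variable)) {
    f <- dataset$fields[[nm]]
    if (is.null(f)) stop("unknown field: ", nm, call. = FALSE)
    if (f$meta$type != "variable") {
      stop("variable filter on non-variable field '", nm, "'", call. = FALSE)
    }
    spec <- params$variable[[nm]]
    pass <- rep(TRUE, n)
    if (!is.null(spec$min)) pass <- pass & f$values >= spec$min
    if (!is.null(spec$max)) pass <- pass & f$values <= spec$max
    if (isTRUE(spec$invert)) pass <- !pass
    mask <- mask & pass
  }
  for (nm in names(params$category)) {
    f <- dataset$fields[[nm]]
    if (is.null(f)) stop("unknown field: ", nm, call. = FALSE)
    if (f$meta$type != "category") {
      stop("category filter on non-category field '", nm, "'", call. = FALSE)
    }
    spec <- params$category[[nm]]
    labels <- f$keys[f$values + 1L]
    inset <- labels %in% spec$keys
    mask <- mask & (if (spec$mode == "include") inset else !inset)
  }
  for (lst in params$id_lists) {
    inset <- dataset$identifiers %in% lst$ids
    mask <- mask & (if (lst$mode == "include") inset else !inset)
  }
  mask
}

subset_field <- function(field, mask) {
  field$values <- if (is.list(field$values)) field$values[mask]
                  else field$values[mask]
  if (field$meta$type == "variable") {
    field$meta$range <- c(min(field$values), max(field$values))
  }
  field
}

#' Subset a dataset by an inclusion mask
#'
#' Identifiers and every field are subset consistently; variable metadata
#' ranges are recomputed. Category keys are retained even when unused so
#' stored indices stay valid. An all-false mask is refused rather than
#' producing an empty dataset.
#'
#' @param dataset A `blobdir`.
#' @param mask Logical vector, one entry per identifier.
#' @return The filtered `blobdir`.
#' @export
filter_dataset <- function(dataset, mask) {
  stopifnot(inherits(dataset, "blobdir"))
  if (length(mask) != length(dataset$identifiers)) {
    stop("mask length ", length(mask), " does not match ",
         length(dataset$identifiers), " identifiers", call. = FALSE)
  }
  if (!any(mask)) stop("empty result: filter retains no contigs", call. = FALSE)
  dataset$identifiers <- dataset$identifiers[mask]
  dataset$fields <- lapply(dataset$fields, subset_field, mask = mask)
  dataset$meta$records <- length(dataset$identifiers)
  dataset$meta$fields <- lapply(dataset$fields, function(f) f$meta)
  names(dataset$meta$fields) <- NULL
  dataset
}

#' Subset a FASTA file by identifier
#'
#' Records are written in input order with sequences unmodified.
#'
#' @param fasta_path Input FASTA.
#' @param ids Identifiers to keep; all must be present in the file.
#' @param out_path Output FASTA path.
#' @return Number of records written, invisibly.
#' @export
filter_fasta <- function(fasta_path, ids, out_path) {
  seqs <- readDNAStringSet(fasta_path)
  names(seqs) <- first_token(names(seqs))
  missing <- setdiff(ids, names(seqs))
  if (length(missing)) {
    stop("id not present in FASTA: ", missing[[1L]], call. = FALSE)
  }
  keep <- seqs[names(seqs) %in% ids]
  writeXStringSet(keep, out_path, width = 80L)
  invisible(length(keep))
}

#' Subset a tabular analysis file by contig id
#'
#' Generic line filter for hit tables, BUSCO full tables and SAM files:
#' records whose contig column matches a retained identifier are kept, and
#' comment/header lines (`#`, or `@` for SAM) are preserved verbatim.
#'
#' @param path Input text file.
#' @param ids Identifiers to retain.
#' @param out_path Output path.
#' @param id_column 1-based index of the contig id column (1 for hit tables'
#'   query id, 3 for BUSCO full tables and SAM reference names).
#' @param comment_prefix Prefixes of lines preserved verbatim.
#' @return Number of data records written, invisibly.
#' @export
filter_records <- function(path, ids, out_path, id_column = 1L,
                           comment_prefix = c("#", "@")) {
  lines <- readLines(path)
  is_comment <- Reduce(`|`, lapply(comment_prefix, startsWith, x = lines),
                       rep(FALSE, length(lines))) | !nzchar(lines)
  keep <- is_comment
  data_idx <- which(!is_comment)
  if (length(data_idx)) {
    fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
    contig <- vapply(fields, function(p) {
      if (length(p) >= id_column) p[[id_column]] else NA_character_
    }, character(1))
    keep[data_idx] <- contig %in% ids
  }
  writeLines(lines[keep], out_path)
  invisible(sum(keep & !is_comment))
}

#' @rdname filter_records
#' @export
filter_hits <- function(path, ids, out_path) {
  filter_records(path, ids, out_path, id_column = 1L, comment_prefix = "#")
}

#' @rdname filter_records
#' @export
filter_sam <- function(path, ids, out_path) {
  filter_records(path, ids, out_path, id_column = 3L, comment_prefix = "@")
}

#' @rdname filter_records
#' @export
filter_busco <- function(path, ids, out_path) {
  filter_records(path, ids, out_path, id_column = 3L, comment_prefix = "#")
}

fmt_num <- function(x) {
  # shortest decimal representation that re-parses to the same double
  for (d in c(15L, 16L, 17L)) {
    s <- format(x, scientific = FALSE, trim = TRUE, digits = d)
    if (as.numeric(s) == x) return(s)
  }
  s
}

#' Encode filter parameters as a reproducible query string
#'
#' Grammar: `<field>--Min=<num>`, `<field>--Max=<num>`, `<field>--Inv=true`,
#' `<field>--Keys=<label>[,<label>...]`. Category key filters are exclude-mode
#' by default; include mode is marked by an `in:` prefix on the key list.
#' Parameters are emitted in canonical order (field id lexicographic; suffix
#' order Min, Max, Inv, Keys) so the encoding is byte-stable. Identifier
#' lists are file-borne, never URL-borne, and are not encoded.
#'
#' @param params A [filter_params()] object.
#' @return Query string (possibly empty).
#' @export
encode_query <- function(params) {
  stopifnot(inherits(params, "filter_params"))
  parts <- character(0)
  for (nm in sort(names(params$variable))) {
    spec <- params$variable[[nm]]
    if (!is.null(spec$min)) parts <- c(parts, paste0(nm, "--Min=", fmt_num(spec$min)))
    if (!is.null(spec$max)) parts <- c(parts, paste0(nm, "--Max=", fmt_num(spec$max)))
    if (isTRUE(spec$invert)) parts <- c(parts, paste0(nm, "--Inv=true"))
  }
  for (nm in sort(names(params$category))) {
    spec <- params$category[[nm]]
    keys <- paste(spec$keys, collapse = ",")
    if (spec$mode == "include") keys <- paste0("in:", keys)
    parts <- c(parts, paste0(nm, "--Keys=", keys))
  }
  paste(parts, collapse = "&")
}

#' Parse a query string (or full URL) into filter parameters
#'
#' Inverse of [encode_query()]. Accepts a bare query string or a full URL
#' (everything up to `?` is discarded). Unknown parameters are ignored with a
#' warning and preserved in the `"unknown"` attribute of the result.
#'
#' @param query Query string or URL.
#' @return A [filter_params()] object.
#' @export
parse_query <- function(query) {
  stopifnot(is.character(query), length(query) == 1L)
  q <- sub("^[^?]*\\?", "", query)
  q <- sub("^#.*$", "", q)
  variable <- list()
  category <- list()
  unknown <- character(0)
  if (nzchar(q)) {
    for (kv in strsplit(q, "&", fixed = TRUE)[[1]]) {
      if (!nzchar(kv)) next
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq == -1L) { unknown <- c(unknown, kv); next }
      key <- substr(kv, 1L, eq - 1L)
      val <- substr(kv, eq + 1L, nchar(kv))
      m <- regmatches(key, regexec("^(.*)--(Min|Max|Inv|Keys)$", key))[[1]]
      if (length(m) != 3L) { unknown <- c(unknown, kv); next }
      fid <- m[2]
      suffix <- m[3]
      if (suffix %in% c("Min", "Max")) {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num)) {
          stop("unparsable numeric in parameter '", key, "'", call. = FALSE)
        }
        variable[[fid]][[tolower(suffix)]] <- num
      } else if (suffix == "Inv") {
        if (identical(tolower(val), "true")) variable[[fid]]$invert <- TRUE
      } else {
        mode <- "exclude"
        if (startsWith(val, "in:")) {
          mode <- "include"
          val <- substring(val, 4L)
        }
        category[[fid]] <- list(keys = strsplit(val, ",", fixed = TRUE)[[1]],
                                mode = mode)
      }
    }
  }
  if (length(unknown)) {
    warning("ignoring unknown query parameter(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- filter_params(variable = variable, category = category)
  attr(out, "unknown") <- unknown
  out
}

#' Percentage of a part in a total, half-up rounded
#'
#' @param part_count,total_count Non-negative counts, `part <= total`,
#'   `total > 0`.
#' @param decimals Decimal places (half-up rounding).
#' @return `100 * part / total` rounded half-up to `decimals`.
#' @export
summarize_percent <- function(part_count, total_count, decimals = 1L) {
  if (total_count <= 0) stop("total must be positive", call. = FALSE)
  if (part_count < 0 || part_count > total_count) {
    stop("part must be between 0 and total", call. = FALSE)
  }
  x <- 100 * part_count / total_count
  scale <- 10^decimals
  floor(x * scale + 0.5) / scale
}

taxon_breakdown <- function(lengths, labels) {
  out <- lapply(split(lengths, labels), function(l) {
    list(span = sum(l), count = length(l), n50 = nx_statistic(l, 0.5))
  })
  out[order(-vapply(out, `[[`, numeric(1), "span"))]
}

#' Export the retained identifier list and filtered summary statistics
#'
#' Produces the importable list document for a set of filters: the complete
#' retained identifier list, the canonical query string, whole-set span /
#' count / N50, the per-taxon breakdown for the active category field and,
#' when BUSCO fields are present, filter-aware BUSCO counts. Applying the
#' exported identifier list as an include filter reproduces the same retained
#' set.
#'
#' @param dataset A `blobdir` with a `length` field.
#' @param params A [filter_params()] object.
#' @param cat_field Category field for the per-taxon breakdown; defaults to
#'   the first category field in the dataset, if any.
#' @param path Optional path; when given the document is written as JSON.
#' @return A list of class `blob_list` with elements `identifiers`, `query`,
#'   `summary`.
#' @export
export_list <- function(dataset, params = filter_params(), cat_field = NULL,
                        path = NULL) {
  mask <- build_mask(dataset, params)
  if (!any(mask)) stop("empty result: filter retains no contigs", call. = FALSE)
  ids <- dataset$identifiers[mask]
  lengths <- variable_values(dataset, "length")[mask]
  summary <- list(span = sum(lengths), count = length(ids),
                  n50 = nx_statistic(lengths, 0.5))
  if (is.null(cat_field)) {
    cats <- names(Filter(function(f) f$meta$type == "category", dataset$fields))
    if (length(cats)) cat_field <- cats[[1L]]
  }
  if (!is.null(cat_field)) {
    labels <- field_values(dataset, cat_field)[mask]
    summary$taxa <- taxon_breakdown(lengths, labels)
    summary$category_field <- cat_field
  }
  busco_fields <- names(Filter(function(f) !is.null(f$meta$busco_total),
                               dataset$fields))
  if (length(busco_fields)) {
    summary$busco <- lapply(setNames(busco_fields, busco_fields), function(fid) {
      lineage <- sub("_busco$", "", fid)
      as.list(busco_summary(dataset, mask, lineage))
    })
  }
  doc <- structure(list(identifiers = ids, query = encode_query(params),
                        summary = summary),
                   class = "blob_list")
  if (!is.null(path)) {
    write_json(list(identifiers = ids, query = doc$query,
                    summary = summary),
               path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  }
  doc
}

#' Import a list document as an identifier filter
#'
#' @param path JSON list document written by [export_list()].
#' @param mode Apply the identifier list as an include (default) or exclude
#'   filter.
#' @return A [filter_params()] object holding the identifier list.
#' @export
import_list <- function(path, mode = "include") {
  doc <- read_json(path, simplifyVector = TRUE)
  filter_params(id_lists = list(list(ids = doc$identifiers, mode = mode)))
}
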