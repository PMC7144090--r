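#' @importFrom jsonlite read_json write_json fromJSON
#' @importFrom stats setNames
NULL

BLOB_FIELD_TYPES <- c("identifier", "variable", "category", "array", "multiarray")

#' The eight taxonomic ranks used for per-contig taxonomy fields
#'
#' NCBI's standard major ranks from superkingdom down to species, the set at
#' which bitscore-sum taxonomic assignments are reported.
#'
#' @return Character vector of eight rank names.
#' @export
blob_ranks <- function() {
  c("superkingdom", "kingdom", "phylum", "class", "order", "family",
    "genus", "species")
}

#' Construct a per-contig field
#'
#' A field is one per-contig attribute column: a `variable` (numeric), a
#' `category` (integer indices into a `keys` vector of labels), an `array`
#' (list of numerics or of key indices per contig) or a `multiarray` (list of
#' rows per contig, e.g. similarity-hit positions). Category indices are
#' 0-based, matching the on-disk JSON representation.
#'
#' @param id Field identifier (also the on-disk file name, `<id>.json`).
#' @param type One of `"identifier"`, `"variable"`, `"category"`, `"array"`,
#'   `"multiarray"`.
#' @param values Per-contig payload; length must equal the number of dataset
#'   identifiers when added to a dataset.
#' @param keys Ordered category labels (category-valued fields only).
#' @param datatype `"integer"`, `"float"` or `"string"`; inferred if `NULL`.
#' @param parent_id,children Optional grouping links to other field ids.
#' @param preload Display hint: load this field by default.
#' @param scale_hint Display hint: `"linear"`, `"sqrt"` or `"log"`.
#' @return An object of class `blob_field`.
#' @export
blob_field <- function(id, type, values, keys = NULL, datatype = NULL,
                       parent_id = NULL, children = NULL, preload = FALSE,
                       scale_hint = "linear") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("field id must be a non-empty string", call. = FALSE)
  }
  type <- match.arg(type, BLOB_FIELD_TYPES)
  if (type == "category") {
    if (is.null(keys)) stop("category field '", id, "' requires keys", call. = FALSE)
    keys <- as.character(keys)
    values <- as.integer(values)
    bad <- values < 0L | values >= length(keys)
    if (any(bad, na.rm = TRUE)) {
      stop("category index out of keys range in field '", id, "'", call. = FALSE)
    }
    if (is.null(datatype)) datatype <- "string"
  } else if (type == "variable") {
    values <- as.numeric(values)
    if (is.null(datatype)) {
      datatype <- if (all(values == floor(values))) "integer" else "float"
    }
  } else if (type == "identifier") {
    values <- as.character(values)
    datatype <- "string"
  } else {
    if (!is.list(values)) stop("'", id, "': ", type, " values must be a list", call. = FALSE)
    if (is.null(datatype)) datatype <- "float"
  }
  meta <- list(id = id, type = type, datatype = datatype,
               preload = isTRUE(preload), scale = scale_hint)
  if (!is.null(parent_id)) meta$parent <- parent_id
  if (!is.null(children)) meta$children <- as.character(children)
  if (type == "variable" && length(values)) {
    meta$range <- c(min(values), max(values))
  }
  structure(list(meta = meta, keys = keys, values = values),
            class = "blob_field")
}

field_length <- function(field) {
  if (is.list(field$values)) length(field$values) else length(field$values)
}

#' Create a new BlobDir dataset
#'
#' The minimal dataset holds only the ordered contig identifiers (stored as an
#' identifier field) plus metadata; further fields are attached with
#' [add_field()].
#'
#' @param identifiers Ordered, unique, non-empty character vector of contig or
#'   scaffold ids.
#' @param meta Optional named list of dataset metadata (assembly block, taxon
#'   block with lineage, hyperlink templates under `links`, `settings`, ...).
#' @return An object of class `blobdir`.
#' @export
create_dataset <- function(identifiers, meta = list()) {
  identifiers <- as.character(identifiers)
  if (length(identifiers) == 0L) {
    stop("cannot create a dataset with no identifiers", call. = FALSE)
  }
  dup <- identifiers[duplicated(identifiers)]
  if (length(dup)) {
    stop("duplicate identifier: ", dup[[1L]], call. = FALSE)
  }
  if (is.null(meta$id)) meta$id <- "dataset"
  if (is.null(meta$record_type)) meta$record_type <- "contig"
  meta$records <- length(identifiers)
  id_field <- blob_field("identifiers", "identifier", identifiers)
  meta$fields <- list(id_field$meta)
  structure(list(meta = meta, identifiers = identifiers,
                 fields = setNames(list(id_field), "identifiers")),
            class = "blobdir")
}

#' @export
print.blobdir <- function(x, ...) {
  cat("BlobDir dataset '", x$meta$id, "': ", length(x$identifiers), " ",
      x$meta$record_type, "s, ", length(x$fields), " fields\n", sep = "")
  for (f in x$fields) {
    extra <- ""
    if (f$meta$type == "variable") {
      extra <- sprintf(" [%g, %g]", f$meta$range[1], f$meta$range[2])
    } else if (f$meta$type == "category") {
      extra <- sprintf(" (%d keys)", length(f$keys))
    }
    cat("  ", format(f$meta$id, width = 20), f$meta$type, extra, "\n", sep = " ")
  }
  invisible(x)
}

#' @export
summary.blobdir <- function(object, ...) {
  lens <- variable_values(object, "length", required = FALSE)
  out <- list(
    id = object$meta$id,
    records = length(object$identifiers),
    fields = vapply(object$fields, function(f) f$meta$type, character(1))
  )
  if (!is.null(lens)) {
    out$span <- sum(lens)
    out$n50 <- nx_statistic(lens, 0.5)
  }
  class(out) <- "summary.blobdir"
  out
}

#' @export
print.summary.blobdir <- function(x, ...) {
  cat("BlobDir dataset '", x$id, "'\n", sep = "")
  cat("  records:", x$records, "\n")
  if (!is.null(x$span)) {
    cat("  span:", format(x$span, big.mark = ","),
        " N50:", format(x$n50, big.mark = ","), "\n")
  }
  cat("  fields:", paste(names(x$fields), collapse = ", "), "\n")
  invisible(x)
}

#' Add (or replace) a field in a dataset
#'
#' The field's length is checked against the dataset identifiers and, for
#' variable fields, the metadata range is recomputed from the observed values
#' rather than trusted from the input.
#'
#' @param dataset A `blobdir` object.
#' @param field A `blob_field`.
#' @param replace Allow replacement of an existing field with the same id.
#' @return The modified `blobdir`.
#' @export
add_field <- function(dataset, field, replace = FALSE) {
  stopifnot(inherits(dataset, "blobdir"), inherits(field, "blob_field"))
  n <- length(dataset$identifiers)
  got <- field_length(field)
  if (got != n) {
    stop("field '", field$meta$id, "' has ", got, " values; expected ", n,
         call. = FALSE)
  }
  id <- field$meta$id
  exists <- id %in% names(dataset$fields)
  if (exists && !isTRUE(replace)) {
    stop("field '", id, "' already present (use replace = TRUE)", call. = FALSE)
  }
  if (field$meta$type == "variable") {
    field$meta$range <- c(min(field$values), max(field$values))
  }
  dataset$fields[[id]] <- field
  metas <- dataset$meta$fields
  ids <- vapply(metas, `[[`, character(1), "id")
  if (exists) {
    metas[[which(ids == id)]] <- field$meta
  } else {
    metas[[length(metas) + 1L]] <- field$meta
  }
  dataset$meta$fields <- metas
  dataset
}

#' Fetch a field's materialised values
#'
#' For category fields the integer indices are translated to their labels.
#'
#' @param dataset A `blobdir`.
#' @param id Field id.
#' @return Numeric vector, character vector (category labels) or list,
#'   depending on the field type.
#' @export
field_values <- function(dataset, id) {
  f <- dataset$fields[[id]]
  if (is.null(f)) stop("unknown field: ", id, call. = FALSE)
  if (f$meta$type == "category") f$keys[f$values + 1L] else f$values
}

variable_values <- function(dataset, id, required = TRUE) {
  f <- dataset$fields[[id]]
  if (is.null(f)) {
    if (required) stop("unknown field: ", id, call. = FALSE)
    return(NULL)
  }
  if (f$meta$type != "variable") {
    if (required) stop("field '", id, "' is not a variable field", call. = FALSE)
    return(NULL)
  }
  f$values
}

field_doc <- function(field) {
  doc <- list(values = field$values)
  if (!is.null(field$keys)) doc$keys <- as.list(field$keys)
  doc
}

#' Write a dataset to a BlobDir directory
#'
#' Layout: `meta.json` (collated field metadata plus dataset metadata),
#' `identifiers.json` and one `<field_id>.json` per additional field, each
#' carrying `values` and, for category-valued fields, `keys`. Numbers are
#' serialised at full precision so a write/read cycle is an identity.
#'
#' @param dataset A `blobdir`.
#' @param path Directory to create (or overwrite files in).
#' @return `path`, invisibly.
#' @export
write_blobdir <- function(dataset, path) {
  stopifnot(inherits(dataset, "blobdir"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_json(dataset$meta, file.path(path, "meta.json"),
             auto_unbox = TRUE, digits = I(17), null = "null", pretty = TRUE)
  for (f in dataset$fields) {
    write_json(field_doc(f), file.path(path, paste0(f$meta$id, ".json")),
               auto_unbox = FALSE, digits = I(17), null = "null")
  }
  invisible(path)
}

coerce_field_values <- function(raw, type, datatype = "float") {
  elem <- if (identical(datatype, "string")) {
    function(v) as.character(unlist(v))
  } else {
    function(v) as.numeric(unlist(v))
  }
  switch(type,
    identifier = vapply(raw, as.character, character(1)),
    variable = vapply(raw, as.numeric, numeric(1)),
    category = vapply(raw, function(v) as.integer(v), integer(1)),
    array = lapply(raw, elem),
    multiarray = lapply(raw, function(contig) lapply(contig, elem))
  )
}

#' Read a BlobDir directory back into a dataset
#'
#' @param path BlobDir directory containing `meta.json`.
#' @return A `blobdir`.
#' @export
read_blobdir <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    stop("not a BlobDir: missing ", meta_path, call. = FALSE)
  }
  meta <- read_json(meta_path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                    simplifyMatrix = FALSE)
  metas <- meta$fields
  fields <- list()
  for (fm in metas) {
    fpath <- file.path(path, paste0(fm$id, ".json"))
    if (!file.exists(fpath)) {
      stop("missing field file: ", basename(fpath), call. = FALSE)
    }
    doc <- read_json(fpath, simplifyVector = FALSE)
    values <- coerce_field_values(doc$values, fm$type, fm$datatype)
    keys <- if (!is.null(doc$keys)) vapply(doc$keys, as.character, character(1))
    f <- blob_field(fm$id, fm$type, values, keys = keys,
                    datatype = fm$datatype,
                    parent_id = fm$parent, children = fm$children,
                    preload = isTRUE(fm$preload),
                    scale_hint = if (is.null(fm$scale)) "linear" else fm$scale)
    for (k in setdiff(names(fm), names(f$meta))) f$meta[[k]] <- fm[[k]]
    if (!is.null(fm$range)) f$meta$range <- as.numeric(unlist(fm$range))
    fields[[fm$id]] <- f
  }
  if (is.null(fields$identifiers)) {
    stop("BlobDir has no identifiers field", call. = FALSE)
  }
  identifiers <- fields$identifiers$values
  meta$fields <- lapply(fields, function(f) f$meta)
  names(meta$fields) <- NULL
  structure(list(meta = meta, identifiers = identifiers, fields = fields),
            class = "blobdir")
}

issue <- function(severity, path, message) {
  data.frame(severity = severity, path = path, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a BlobDir directory against the format contract
#'
#' Dynamic validation: document parsability, presence of every file referenced
#' by the metadata, absence of orphan field files, declared-vs-actual
#' datatypes, value-array lengths against the identifier count, category
#' indices against key lists and metadata ranges against observed values.
#' Structural problems are reported as errors; display-hint oddities (an
#' unknown `scale` value) as warnings.
#'
#' @param path BlobDir directory.
#' @return An object of class `blobdir_validation`: list with `ok` (no
#'   error-severity issues) and `issues` (data frame of severity, path,
#'   message).
#' @export
validate_blobdir <- function(path) {
  issues <- list()
  add <- function(severity, where, msg) {
    issues[[length(issues) + 1L]] <<- issue(severity, where, msg)
  }
  finish <- function() {
    df <- if (length(issues)) do.call(rbind, issues) else
      issue(character(0), character(0), character(0))
    structure(list(ok = !any(df$severity == "error"), issues = df),
              class = "blobdir_validation")
  }
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    add("error", "meta.json", "metadata document missing")
    return(finish())
  }
  meta <- tryCatch(
    read_json(meta_path, simplifyVector = FALSE),
    error = function(e) {
      add("error", "meta.json", paste("unparsable:", conditionMessage(e)))
      NULL
    })
  if (is.null(meta)) return(finish())
  metas <- meta$fields
  ids <- vapply(metas, function(m) as.character(m$id), character(1))
  if (anyDuplicated(ids)) {
    add("error", "meta.json", paste("duplicate field id:",
                                    ids[duplicated(ids)][1]))
  }
  for (m in metas) {
    if (!is.null(m$children)) {
      missing_child <- setdiff(unlist(m$children), ids)
      if (length(missing_child)) {
        add("error", "meta.json",
            paste0("field '", m$id, "' references unknown child '",
                   missing_child[1], "'"))
      }
    }
    sc <- m$scale
    if (!is.null(sc) && !sc %in% c("linear", "sqrt", "log", "scaleLog",
                                   "scaleLinear", "scaleSqrt")) {
      add("warning", paste0(m$id, ".json"),
          paste0("unknown scale hint '", sc, "'"))
    }
  }
  json_files <- setdiff(basename(list.files(path, pattern = "\\.json$")),
                        "meta.json")
  orphans <- setdiff(sub("\\.json$", "", json_files), ids)
  for (o in orphans) {
    add("error", paste0(o, ".json"), "orphan field file not in metadata")
  }
  n_ids <- NA_integer_
  docs <- list()
  for (m in metas) {
    fpath <- file.path(path, paste0(m$id, ".json"))
    if (!file.exists(fpath)) {
      add("error", paste0(m$id, ".json"), "field file missing")
      next
    }
    doc <- tryCatch(read_json(fpath, simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(doc)) {
      add("error", paste0(m$id, ".json"), "unparsable field document")
      next
    }
    if (is.null(doc$values)) {
      add("error", paste0(m$id, ".json"), "field document lacks 'values'")
      next
    }
    docs[[m$id]] <- doc
    if (identical(m$id, "identifiers")) n_ids <- length(doc$values)
  }
  if (is.na(n_ids)) {
    add("error", "identifiers.json", "identifiers field missing")
    return(finish())
  }
  id_values <- unlist(docs$identifiers$values)
  if (anyDuplicated(id_values)) {
    add("error", "identifiers.json",
        paste("duplicate identifier:", id_values[duplicated(id_values)][1]))
  }
  for (m in metas) {
    doc <- docs[[m$id]]
    if (is.null(doc)) next
    where <- paste0(m$id, ".json")
    if (length(doc$values) != n_ids) {
      add("error", where, sprintf("%d values for %d identifiers",
                                  length(doc$values), n_ids))
      next
    }
    type <- m$type
    flat <- doc$values
    if (type %in% c("variable", "category")) {
      non_scalar <- vapply(flat, function(v) length(unlist(v)) != 1L, logical(1))
      if (any(non_scalar)) {
        add("error", where, "non-scalar entry in scalar field")
        next
      }
      vals <- unlist(flat)
      if (type == "variable") {
        if (!is.numeric(vals)) {
          add("error", where, "declared variable but values are not numeric")
          next
        }
        if (identical(m$datatype, "integer") && any(vals != floor(vals))) {
          add("error", where, "declared integer but non-integer values present")
        }
        rng <- as.numeric(unlist(m$range))
        if (length(rng) != 2L) {
          add("error", where, "variable field lacks a [min, max] range")
        } else if (rng[1] > rng[2]) {
          add("error", where, "range minimum exceeds maximum")
        } else if (min(vals) < rng[1] || max(vals) > rng[2]) {
          add("error", where,
              sprintf("metadata range [%g, %g] does not cover observed [%g, %g]",
                      rng[1], rng[2], min(vals), max(vals)))
        }
      } else {
        keys <- unlist(doc$keys)
        if (is.null(keys)) {
          add("error", where, "category field lacks keys")
        } else if (!is.numeric(vals) || any(vals != floor(vals))) {
          add("error", where, "category values must be integer indices")
        } else if (any(vals < 0 | vals >= length(keys))) {
          add("error", where, "category index out of keys range")
        }
      }
    }
  }
  finish()
}

#' @export
print.blobdir_validation <- function(x, ...) {
  cat(if (x$ok) "valid BlobDir" else "INVALID BlobDir", "-",
      nrow(x$issues), "issue(s)\n")
  if (nrow(x$issues)) {
    print(x$issues, row.names = FALSE)
  }
  invisible(x)
}

#' Expand a hyperlink template
#'
#' Substitutes `{placeholder}` tokens verbatim from a context map; used for
#' the dataset-, identifier- and hit-scoped hyperlink templates carried in
#' BlobDir metadata.
#'
#' @param template Template string, e.g. `"https://x/{accession}"`.
#' @param context Named list or character vector of placeholder values.
#' @return The expanded URL string.
#' @export
expand_link <- function(template, context = list()) {
  stopifnot(is.character(template), length(template) == 1L)
  m <- gregexpr("\\{([^{}]+)\\}", template)[[1]]
  if (m[1] == -1L) return(template)
  tokens <- unique(regmatches(template, gregexpr("\\{([^{}]+)\\}", template))[[1]])
  names_needed <- gsub("[{}]", "", tokens)
  missing <- setdiff(names_needed, names(context))
  if (length(missing)) {
    stop("unresolved placeholder: ", missing[[1L]], call. = FALSE)
  }
  out <- template
  for (nm in names_needed) {
    out <- gsub(paste0("{", nm, "}"), as.character(context[[nm]]),
                out, fixed = TRUE)
  }
  out
}
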