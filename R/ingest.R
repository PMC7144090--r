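#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   letterFrequency subseq width
#' @importFrom Rsamtools asBam scanBamHeader ScanBamParam scanBamFlag
#' @importFrom GenomicAlignments readGAlignments cigar
#' @importFrom S4Vectors mcols
#' @importFrom utils head
NULL

first_token <- function(x) sub("[ \t].*$", "", x)

#' Per-sequence assembly statistics from a FASTA file
#'
#' Computes, per record and in file order: length, GC proportion and the
#' proportion of undefined (N) bases. GC is computed over unambiguous bases
#' only, `(G + C) / (A + C + G + T)`, case-insensitively; N proportion uses
#' the full sequence length. Other IUPAC ambiguity codes count toward length
#' but are excluded from the GC denominator.
#'
#' @param fasta_path Path to a (multi-line) FASTA file.
#' @return A data frame with columns `id`, `length`, `gc`, `n`.
#' @export
parse_fasta_stats <- function(fasta_path) {
  seqs <- readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("no FASTA records in ", fasta_path, call. = FALSE)
  ids <- first_token(names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  if (any(width(seqs) == 0L)) {
    stop("empty sequence record: ", ids[width(seqs) == 0L][1], call. = FALSE)
  }
  freq <- letterFrequency(seqs, letters = c("A", "C", "G", "T", "N"))
  acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- ifelse(acgt > 0, rowSums(freq[, c("G", "C"), drop = FALSE]) / acgt, 0)
  data.frame(id = ids, length = width(seqs), gc = as.numeric(gc),
             n = as.numeric(freq[, "N"] / width(seqs)),
             stringsAsFactors = FALSE)
}

#' Base and read coverage per contig from a read alignment file
#'
#' Read coverage is the count of mapped, primary, non-supplementary alignment
#' records per contig; base coverage is the sum of aligned read bases
#' (reference-consuming CIGAR operations M, = and X) divided by the contig
#' length. Contigs with no alignments are reported with zeros. SAM input is
#' converted on the fly; BAM is read directly.
#'
#' @param alignment_path SAM (`.sam`) or BAM file.
#' @param contig_lengths Named numeric vector of contig lengths; the alignment
#'   header may reference only these contigs.
#' @param library_id Optional label recorded in the result.
#' @return Data frame with columns `id`, `base_cov`, `read_cov`, `library_id`,
#'   ordered as `contig_lengths`.
#' @export
parse_alignment_coverage <- function(alignment_path, contig_lengths,
                                     library_id = NULL) {
  stopifnot(!is.null(names(contig_lengths)))
  bam <- alignment_path
  if (grepl("\\.sam$", alignment_path, ignore.case = TRUE)) {
    bam <- asBam(alignment_path, tempfile(), overwrite = TRUE,
                 indexDestination = FALSE)
  }
  header_targets <- scanBamHeader(bam)[[1]]$targets
  unknown <- setdiff(names(header_targets), names(contig_lengths))
  if (length(unknown)) {
    stop("alignment references unknown contig: ", unknown[[1L]], call. = FALSE)
  }
  param <- ScanBamParam(flag = scanBamFlag(isUnmappedQuery = FALSE,
                                           isSecondaryAlignment = FALSE,
                                           isSupplementaryAlignment = FALSE))
  ga <- readGAlignments(bam, param = param)
  ids <- names(contig_lengths)
  read_cov <- setNames(integer(length(ids)), ids)
  aligned <- setNames(numeric(length(ids)), ids)
  if (length(ga)) {
    seqn <- as.character(GenomicAlignments::seqnames(ga))
    ops <- GenomicAlignments::cigarOpTable(cigar(ga))
    per_read <- rowSums(ops[, c("M", "=", "X"), drop = FALSE])
    tab <- table(seqn)
    read_cov[names(tab)] <- as.integer(tab)
    sums <- tapply(per_read, seqn, sum)
    aligned[names(sums)] <- as.numeric(sums)
  }
  data.frame(id = ids, base_cov = aligned / as.numeric(contig_lengths),
             read_cov = as.integer(read_cov),
             library_id = if (is.null(library_id)) NA_character_ else library_id,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Parse BLAST/Diamond-style tabular hits
#'
#' Reads outfmt-6-style tab-separated hits with a configurable column order.
#' Recognised column names: `qseqid`, `staxids`, `bitscore`, `sseqid`,
#' `qstart`, `qend`; further columns are ignored. Multi-taxid cells
#' (semicolon-separated) keep the first taxid; rows with taxid 0 or an
#' unparsable taxid are dropped with a reported count.
#'
#' @param path Tab-separated hits file; lines starting with `#` are skipped.
#' @param columns Character vector naming the file's columns in order
#'   (default `c("qseqid", "staxids", "bitscore")`).
#' @param db_index 0-based priority order of the source database.
#' @return Data frame with columns `query_id`, `taxid`, `bitscore`,
#'   `subject_id`, `qstart`, `qend`, `db_index`.
#' @export
parse_tabular_hits <- function(path,
                               columns = c("qseqid", "staxids", "bitscore"),
                               db_index = 0L) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  empty <- data.frame(query_id = character(0), taxid = integer(0),
                      bitscore = numeric(0), subject_id = character(0),
                      qstart = integer(0), qend = integer(0),
                      db_index = integer(0), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, integer(1)) < length(columns))
  if (length(short)) {
    stop("malformed hit row (too few columns) at line ", short[[1L]],
         call. = FALSE)
  }
  col <- function(name) {
    idx <- match(name, columns)
    if (is.na(idx)) return(NULL)
    vapply(parts, `[[`, character(1), idx)
  }
  taxid_raw <- col("staxids")
  if (is.null(taxid_raw) || is.null(col("qseqid")) || is.null(col("bitscore"))) {
    stop("columns must include qseqid, staxids and bitscore", call. = FALSE)
  }
  taxid <- suppressWarnings(
    as.integer(vapply(strsplit(taxid_raw, ";", fixed = TRUE), `[[`,
                      character(1), 1L)))
  hits <- data.frame(
    query_id = col("qseqid"),
    taxid = taxid,
    bitscore = as.numeric(col("bitscore")),
    subject_id = if (is.null(col("sseqid"))) NA_character_ else col("sseqid"),
    qstart = if (is.null(col("qstart"))) NA_integer_ else as.integer(col("qstart")),
    qend = if (is.null(col("qend"))) NA_integer_ else as.integer(col("qend")),
    db_index = as.integer(db_index),
    stringsAsFactors = FALSE)
  drop <- is.na(hits$taxid) | hits$taxid == 0L
  if (any(drop)) {
    message("dropped ", sum(drop), " hit(s) with missing or zero taxid")
    hits <- hits[!drop, , drop = FALSE]
    rownames(hits) <- NULL
  }
  hits
}

parse_dmp <- function(path) {
  lines <- readLines(path)
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t|\t", fixed = TRUE)
}

#' Read an NCBI-style taxdump
#'
#' Parses the pipe-delimited `nodes.dmp` (taxid, parent, rank) and `names.dmp`
#' (scientific names only) dialect into lookup tables.
#'
#' @param dir Directory containing `nodes.dmp` and `names.dmp`; alternatively
#'   pass both paths explicitly.
#' @param nodes_path,names_path Explicit file paths (override `dir`).
#' @return An object of class `taxdump`: named lookups `parent`, `rank`,
#'   `name` keyed by taxid.
#' @export
read_taxdump <- function(dir = NULL, nodes_path = NULL, names_path = NULL) {
  if (!is.null(dir)) {
    if (is.null(nodes_path)) nodes_path <- file.path(dir, "nodes.dmp")
    if (is.null(names_path)) names_path <- file.path(dir, "names.dmp")
  }
  nodes <- parse_dmp(nodes_path)
  taxid <- vapply(nodes, `[[`, character(1), 1L)
  parent <- vapply(nodes, `[[`, character(1), 2L)
  rank <- vapply(nodes, `[[`, character(1), 3L)
  nm <- parse_dmp(names_path)
  keep <- vapply(nm, function(x) length(x) >= 4L && x[[4L]] == "scientific name",
                 logical(1))
  nm <- nm[keep]
  name <- setNames(vapply(nm, `[[`, character(1), 2L),
                   vapply(nm, `[[`, character(1), 1L))
  root <- taxid[taxid == parent]
  if (!length(root)) stop("taxdump has no self-parented root", call. = FALSE)
  structure(list(parent = setNames(parent, taxid),
                 rank = setNames(rank, taxid),
                 name = name),
            class = "taxdump")
}

#' Resolve a taxid's lineage at the requested ranks
#'
#' Walks parent links from the taxid to the root, recording the scientific
#' name of the ancestor (or the node itself) at each requested rank. Ranks
#' with no ancestor in the lineage map to `"undefined"`.
#'
#' @param taxid Integer or string taxid present in the taxdump.
#' @param taxdump A [read_taxdump()] object.
#' @param ranks Character vector of rank names (default [blob_ranks()]).
#' @return Named character vector, one name per requested rank.
#' @export
lineage_at_ranks <- function(taxid, taxdump, ranks = blob_ranks()) {
  key <- as.character(taxid)
  if (!key %in% names(taxdump$parent)) {
    stop("unknown taxid: ", key, call. = FALSE)
  }
  out <- setNames(rep("undefined", length(ranks)), ranks)
  cur <- key
  seen <- character(0)
  repeat {
    if (cur %in% seen) stop("cycle in taxdump at taxid ", cur, call. = FALSE)
    seen <- c(seen, cur)
    r <- taxdump$rank[[cur]]
    if (r %in% ranks && identical(out[[r]], "undefined")) {
      nm <- taxdump$name[cur]
      out[[r]] <- if (is.na(nm)) paste0("taxid-", cur) else unname(nm)
    }
    nxt <- taxdump$parent[[cur]]
    if (is.null(nxt) || is.na(nxt)) stop("broken parent link at taxid ", cur,
                                         call. = FALSE)
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  out
}

#' Assign per-contig taxonomy with a bitscore-sum taxrule
#'
#' For each contig and rank, every hit's taxid is mapped to a taxon name at
#' that rank and bitscores are summed per taxon. `bestsum` pools hits from all
#' databases; `bestsumorder` uses, per contig, only the first database (in
#' priority order) that produced at least one hit. The winning taxon is the
#' one with the highest summed bitscore (ties break to the lexicographically
#' smallest name); the c-index counts the alternate positively-scoring taxa
#' at that rank. Contigs without hits are assigned `"no-hit"` with score 0 and
#' c-index 0.
#'
#' @param hit_sets A data frame of hits (see [parse_tabular_hits()]) or a list
#'   of such data frames in database priority order.
#' @param taxdump A [read_taxdump()] object; hits whose taxid is absent are
#'   dropped with a reported count.
#' @param identifiers Dataset contig ids; every hit must name one of these.
#' @param taxrule `"bestsum"` or `"bestsumorder"`.
#' @param ranks Ranks to assign at (default [blob_ranks()]).
#' @return A list with `assignments` (per rank: `taxon`, `score`, `cindex`
#'   vectors over contigs plus `hit_names`, the per-contig taxon name of every
#'   hit in input order) and `positions` (per contig, a matrix of
#'   `qstart`, `qend`, `taxid`, `bitscore` for every hit).
#' @export
apply_taxrule <- function(hit_sets, taxdump, identifiers,
                          taxrule = c("bestsum", "bestsumorder"),
                          ranks = blob_ranks()) {
  taxrule <- match.arg(taxrule)
  if (is.data.frame(hit_sets)) hit_sets <- list(hit_sets)
  for (i in seq_along(hit_sets)) {
    hit_sets[[i]]$db_order <- rep(i, nrow(hit_sets[[i]]))
  }
  hits <- do.call(rbind, hit_sets)
  if (is.null(hits) || !nrow(hits)) {
    hits <- data.frame(query_id = character(0), taxid = integer(0),
                       bitscore = numeric(0), qstart = integer(0),
                       qend = integer(0), db_order = integer(0))
  }
  unknown_q <- setdiff(hits$query_id, identifiers)
  if (length(unknown_q)) {
    stop("hit for unknown contig: ", unknown_q[[1L]], call. = FALSE)
  }
  known <- as.character(hits$taxid) %in% names(taxdump$parent)
  if (any(!known)) {
    message("dropped ", sum(!known), " hit(s) with unknown taxid")
    hits <- hits[known, , drop = FALSE]
  }
  uniq_tax <- unique(as.character(hits$taxid))
  lineage <- matrix("undefined", nrow = length(uniq_tax), ncol = length(ranks),
                    dimnames = list(uniq_tax, ranks))
  for (t in uniq_tax) lineage[t, ] <- lineage_at_ranks(t, taxdump, ranks)
  n <- length(identifiers)
  assignments <- lapply(ranks, function(r) {
    list(taxon = rep("no-hit", n), score = numeric(n), cindex = integer(n),
         hit_names = vector("list", n))
  })
  names(assignments) <- ranks
  positions <- vector("list", n)
  names(positions) <- identifiers
  by_contig <- split(seq_len(nrow(hits)), factor(hits$query_id,
                                                 levels = identifiers))
  for (i in seq_len(n)) {
    idx <- by_contig[[i]]
    if (!length(idx)) {
      positions[[i]] <- matrix(numeric(0), ncol = 4,
                               dimnames = list(NULL, c("qstart", "qend",
                                                       "taxid", "bitscore")))
      for (r in ranks) assignments[[r]]$hit_names[[i]] <- character(0)
      next
    }
    idx <- idx[order(hits$db_order[idx])]
    h <- hits[idx, , drop = FALSE]
    positions[[i]] <- cbind(qstart = as.numeric(h$qstart),
                            qend = as.numeric(h$qend),
                            taxid = as.numeric(h$taxid),
                            bitscore = h$bitscore)
    scored <- h
    if (taxrule == "bestsumorder") {
      scored <- h[h$db_order == min(h$db_order), , drop = FALSE]
    }
    for (r in ranks) {
      nm_all <- lineage[as.character(h$taxid), r]
      assignments[[r]]$hit_names[[i]] <- unname(nm_all)
      nm <- lineage[as.character(scored$taxid), r]
      sums <- tapply(scored$bitscore, nm, sum)
      winners <- names(sums)[sums == max(sums)]
      assignments[[r]]$taxon[i] <- sort(winners)[1L]
      assignments[[r]]$score[i] <- max(sums)
      assignments[[r]]$cindex[i] <- sum(sums > 0) - 1L
    }
  }
  list(assignments = assignments, positions = positions, taxrule = taxrule)
}

#' Attach taxrule results to a dataset as fields
#'
#' Creates, per rank, a category field `<taxrule>_<rank>` plus variable fields
#' `<taxrule>_<rank>_score` and `<taxrule>_<rank>_cindex`, and one multiarray
#' field `<taxrule>_positions` holding (qstart, qend, taxid, bitscore) rows
#' per hit.
#'
#' @param dataset A `blobdir`.
#' @param tax Result of [apply_taxrule()].
#' @param replace Passed to [add_field()].
#' @return The modified `blobdir`.
#' @export
add_taxonomy_fields <- function(dataset, tax, replace = FALSE) {
  prefix <- tax$taxrule
  rank_ids <- paste0(prefix, "_", names(tax$assignments))
  for (r in names(tax$assignments)) {
    a <- tax$assignments[[r]]
    keys <- sort(unique(c("no-hit", a$taxon)))
    fid <- paste0(prefix, "_", r)
    dataset <- add_field(dataset, blob_field(
      fid, "category", match(a$taxon, keys) - 1L, keys = keys,
      parent_id = prefix,
      children = paste0(fid, c("_score", "_cindex", "_hits"))),
      replace = replace)
    dataset <- add_field(dataset, blob_field(
      paste0(fid, "_score"), "variable", a$score, parent_id = fid),
      replace = replace)
    dataset <- add_field(dataset, blob_field(
      paste0(fid, "_cindex"), "variable", a$cindex, parent_id = fid),
      replace = replace)
    keys_h <- sort(unique(c("no-hit", unlist(a$hit_names))))
    vals_h <- lapply(a$hit_names, function(nm) as.integer(match(nm, keys_h)) - 1L)
    dataset <- add_field(dataset, blob_field(
      paste0(fid, "_hits"), "array", vals_h, keys = keys_h,
      datatype = "integer", parent_id = fid), replace = replace)
  }
  pos <- lapply(tax$positions, function(m) {
    lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  })
  dataset <- add_field(dataset, blob_field(
    paste0(prefix, "_positions"), "multiarray", pos, datatype = "float",
    parent_id = prefix), replace = replace)
  dataset$meta$taxrule <- prefix
  dataset
}

BUSCO_STATUSES <- c("Complete", "Duplicated", "Fragmented", "Missing")

#' Parse a BUSCO full-table TSV
#'
#' @param path BUSCO full table; comment lines start with `#`. Columns:
#'   busco id, status, contig (absent for Missing), optional start/end.
#' @param lineage_id Label of the BUSCO lineage set (e.g. `"diptera_odb9"`).
#' @return List with `records` (data frame `busco_id`, `status`, `contig_id`,
#'   `start`, `end`, `lineage_id`), `total` (count of distinct busco ids,
#'   Missing included) and `counts` (ids per status, each id counted once;
#'   an id Complete on several contigs counts as Duplicated).
#' @export
parse_busco_table <- function(path, lineage_id) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    records <- data.frame(busco_id = character(0), status = character(0),
                          contig_id = character(0), start = integer(0),
                          end = integer(0), lineage_id = character(0),
                          stringsAsFactors = FALSE)
    return(list(records = records, total = 0L,
                counts = setNames(integer(4), BUSCO_STATUSES)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(p, i) if (length(p) >= i && nzchar(p[[i]])) p[[i]] else NA
  status <- vapply(parts, function(p) as.character(get(p, 2L)), character(1))
  bad <- which(!status %in% BUSCO_STATUSES)
  if (length(bad)) {
    stop("unknown BUSCO status '", status[bad[1L]], "' at line ",
         lineno[bad[1L]], call. = FALSE)
  }
  records <- data.frame(
    busco_id = vapply(parts, function(p) as.character(get(p, 1L)), character(1)),
    status = status,
    contig_id = vapply(parts, function(p) as.character(get(p, 3L)), character(1)),
    start = suppressWarnings(vapply(parts, function(p) as.integer(get(p, 4L)),
                                    integer(1))),
    end = suppressWarnings(vapply(parts, function(p) as.integer(get(p, 5L)),
                                  integer(1))),
    lineage_id = lineage_id, stringsAsFactors = FALSE)
  if (any(records$status == "Missing" & !is.na(records$contig_id))) {
    stop("Missing BUSCO record carries a contig", call. = FALSE)
  }
  ids <- unique(records$busco_id)
  status_of <- vapply(ids, function(b) {
    st <- records$status[records$busco_id == b]
    if (sum(st %in% c("Complete", "Duplicated")) >= 2L || "Duplicated" %in% st) {
      "Duplicated"
    } else if ("Complete" %in% st) "Complete"
    else if ("Fragmented" %in% st) "Fragmented"
    else "Missing"
  }, character(1))
  counts <- vapply(BUSCO_STATUSES, function(s) sum(status_of == s), integer(1))
  list(records = records, total = length(ids), counts = counts)
}

#' Attach a BUSCO lineage to a dataset
#'
#' Stores one multiarray field `<lineage>_busco` whose per-contig entries are
#' `(busco_id, status)` pairs, with the lineage totals in the field metadata
#' (used by [busco_summary()] to recompute counts under filters).
#'
#' @param dataset A `blobdir`.
#' @param busco Result of [parse_busco_table()].
#' @param replace Passed to [add_field()].
#' @return The modified `blobdir`.
#' @export
add_busco_field <- function(dataset, busco, replace = FALSE) {
  lineage <- busco$records$lineage_id[1]
  if (is.na(lineage) || is.null(lineage)) lineage <- "busco"
  recs <- busco$records
  unknown <- setdiff(recs$contig_id[!is.na(recs$contig_id)],
                     dataset$identifiers)
  if (length(unknown)) {
    stop("BUSCO record for unknown contig: ", unknown[[1L]], call. = FALSE)
  }
  per_contig <- lapply(dataset$identifiers, function(id) {
    rows <- which(recs$contig_id == id & !is.na(recs$contig_id))
    lapply(rows, function(i) c(recs$busco_id[i], recs$status[i]))
  })
  fid <- paste0(lineage, "_busco")
  f <- blob_field(fid, "multiarray", per_contig, datatype = "string")
  f$meta$busco_total <- busco$total
  f$meta$busco_counts <- as.list(busco$counts)
  f$meta$busco_ids <- as.list(unique(recs$busco_id))
  add_field(dataset, f, replace = replace)
}

#' Split long sequences into near-equal chunks
#'
#' Sequences strictly longer than `chunk_len` are split into
#' `min(ceiling(length / chunk_len), max_chunks)` contiguous chunks whose
#' lengths differ by at most one base, so taxonomic inference for long contigs
#' does not depend on a single region. Chunk ids are `<id>_<ordinal>`
#' (0-based). Shorter sequences pass through unchanged.
#'
#' @param fasta_path Input FASTA.
#' @param out_path Optional path for the chunked FASTA.
#' @param chunk_len Split threshold in bases (default 100000).
#' @param max_chunks Maximum chunks per sequence (default 10).
#' @return List with `sequences` (a `DNAStringSet`) and `chunk_map` (data
#'   frame `chunk_id`, `original_id`, `offset` (0-based), `chunk_length`;
#'   unsplit sequences appear as their own single chunk).
#' @export
split_long_sequences <- function(fasta_path, out_path = NULL,
                                 chunk_len = 100000L, max_chunks = 10L) {
  stopifnot(chunk_len > 0, max_chunks >= 1)
  seqs <- readDNAStringSet(fasta_path)
  names(seqs) <- first_token(names(seqs))
  out_seqs <- list()
  rows <- list()
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    len <- width(seqs)[i]
    if (len <= chunk_len) {
      out_seqs[[id]] <- seqs[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        chunk_id = id, original_id = id, offset = 0, chunk_length = len,
        stringsAsFactors = FALSE)
      next
    }
    k <- min(ceiling(len / chunk_len), max_chunks)
    base <- len %/% k
    sizes <- rep(base, k) + c(rep(1L, len %% k), rep(0L, k - len %% k))
    offset <- 0
    for (j in seq_len(k)) {
      cid <- paste0(id, "_", j - 1L)
      out_seqs[[cid]] <- subseq(seqs[[i]], offset + 1L, offset + sizes[j])
      rows[[length(rows) + 1L]] <- data.frame(
        chunk_id = cid, original_id = id, offset = offset,
        chunk_length = sizes[j], stringsAsFactors = FALSE)
      offset <- offset + sizes[j]
    }
  }
  result <- DNAStringSet(out_seqs)
  if (!is.null(out_path)) writeXStringSet(result, out_path)
  list(sequences = result, chunk_map = do.call(rbind, rows))
}

#' Map hits on chunk ids back to original sequence ids
#'
#' Replaces chunk query ids by the original id, shifting query coordinates by
#' the chunk offset; bitscores are untouched. Ids absent from the chunk map
#' are an error.
#'
#' @param hits Data frame of hits ([parse_tabular_hits()] layout).
#' @param chunk_map Chunk map from [split_long_sequences()].
#' @return The hits with `query_id`, `qstart`, `qend` rewritten.
#' @export
merge_chunk_hits <- function(hits, chunk_map) {
  if (!nrow(hits)) return(hits)
  idx <- match(hits$query_id, chunk_map$chunk_id)
  if (anyNA(idx)) {
    stop("unknown chunk id: ", hits$query_id[which(is.na(idx))[1]],
         call. = FALSE)
  }
  hits$query_id <- chunk_map$original_id[idx]
  shift <- chunk_map$offset[idx]
  hits$qstart <- hits$qstart + as.integer(shift)
  hits$qend <- hits$qend + as.integer(shift)
  hits
}

#' Identifiers with no similarity hits
#'
#' Used to restrict a second-pass (e.g. protein-level) search to contigs the
#' first search failed to annotate.
#'
#' @param hits Data frame of hits.
#' @param identifiers Dataset contig ids, in order.
#' @return The hitless identifiers, in dataset order.
#' @export
extract_nohit_ids <- function(hits, identifiers) {
  identifiers[!identifiers %in% hits$query_id]
}

#' Read-subsampling proportion for a target maximum coverage
#'
#' `min(1, max_cov * assembly_span / total_read_bases)`: the fraction of reads
#' to keep so the expected coverage does not exceed `max_cov`.
#'
#' @param total_read_bases Total bases in the read set.
#' @param assembly_span Assembly span in bases.
#' @param max_cov Target maximum coverage (default 100).
#' @return Proportion in (0, 1].
#' @export
subsample_proportion <- function(total_read_bases, assembly_span,
                                 max_cov = 100) {
  if (any(c(total_read_bases, assembly_span, max_cov) <= 0)) {
    stop("all arguments must be positive", call. = FALSE)
  }
  min(1, max_cov * assembly_span / total_read_bases)
}
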