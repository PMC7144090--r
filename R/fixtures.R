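#' @importFrom stats rlnorm rnorm runif
NULL

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Describe one synthetic assembly component
#'
#' A component is one organism mixed into the synthetic assembly: the target
#' genome, a contaminant or a cobiont. Contig lengths are log-normal, base
#' composition is i.i.d. with per-contig GC drawn around `gc_mean`, and
#' coverage is uniform at `cov_mean`.
#'
#' @param label Component label, used as the contig id prefix.
#' @param taxid True taxid of the component in the mini taxdump.
#' @param gc_mean,gc_sd Per-contig GC proportion distribution (feasibility
#'   requires `gc_mean +/- 3 gc_sd` inside [0, 1]).
#' @param cov_mean Target read coverage.
#' @param n_contigs Number of contigs.
#' @param length_meanlog,length_sdlog Log-normal contig length parameters.
#' @param hit_rate Fraction of contigs receiving similarity hits.
#' @param hit_noise Fraction of hits pointing to a wrong taxid.
#' @return A `component_spec` list.
#' @export
component_spec <- function(label, taxid, gc_mean, cov_mean, n_contigs,
                           gc_sd = 0.02, length_meanlog = log(1500),
                           length_sdlog = 0.4, hit_rate = 1, hit_noise = 0) {
  if (gc_mean < 0 || gc_mean > 1 || hit_rate < 0 || hit_rate > 1 ||
      hit_noise < 0 || hit_noise > 1) {
    stop("rates and proportions must lie in [0, 1]", call. = FALSE)
  }
  if (cov_mean < 0) stop("cov_mean must be non-negative", call. = FALSE)
  if (gc_mean - 3 * gc_sd < 0 || gc_mean + 3 * gc_sd > 1) {
    stop("infeasible component: gc_mean +/- 3 gc_sd outside [0, 1]",
         call. = FALSE)
  }
  structure(list(label = label, taxid = taxid, gc_mean = gc_mean,
                 gc_sd = gc_sd, cov_mean = cov_mean, n_contigs = n_contigs,
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 hit_rate = hit_rate, hit_noise = hit_noise),
            class = "component_spec")
}

random_sequence <- function(len, gc) {
  is_gc <- runif(len) < gc
  u <- runif(len) < 0.5
  bases <- character(len)
  bases[is_gc & u] <- "G"
  bases[is_gc & !u] <- "C"
  bases[!is_gc & u] <- "A"
  bases[!is_gc & !u] <- "T"
  paste(bases, collapse = "")
}

#' Generate a synthetic mixed assembly with planted truth
#'
#' Emits one FASTA record per contig and a truth table recording, per contig,
#' the component it came from, its true taxid, length, target GC and target
#' coverage (plus the component's hit rate/noise, used by [make_hits()]).
#' Byte-identical output for a given seed.
#'
#' @param components List of [component_spec()]s.
#' @param seed Integer seed.
#' @param fasta_path Optional path to write the FASTA.
#' @return List with `sequences` (a `DNAStringSet`) and `truth` (data frame).
#' @export
make_assembly <- function(components, seed, fasta_path = NULL) {
  stopifnot(length(components) >= 1L)
  with_seed(seed, {
    seqs <- list()
    rows <- list()
    for (comp in components) {
      for (i in seq_len(comp$n_contigs)) {
        id <- paste0(comp$label, "_", i)
        len <- max(200L, as.integer(round(
          rlnorm(1, comp$length_meanlog, comp$length_sdlog))))
        gc <- min(1, max(0, rnorm(1, comp$gc_mean, comp$gc_sd)))
        seqs[[id]] <- random_sequence(len, gc)
        rows[[length(rows) + 1L]] <- data.frame(
          id = id, label = comp$label, taxid = comp$taxid, length = len,
          gc = gc, cov = comp$cov_mean, hit_rate = comp$hit_rate,
          hit_noise = comp$hit_noise, stringsAsFactors = FALSE)
      }
    }
    sequences <- DNAStringSet(unlist(seqs))
    truth <- do.call(rbind, rows)
    if (!is.null(fasta_path)) writeXStringSet(sequences, fasta_path, width = 80L)
    list(sequences = sequences, truth = truth)
  })
}

#' Generate an error-free SAM alignment hitting target coverages exactly
#'
#' Per contig, `round(cov * length / read_length)` fully aligned
#' (`<read_length>M`) reads are placed at uniform positions, so the base
#' coverage recovered from the file matches the target up to the rounding of
#' the read count. The header lists every contig.
#'
#' @param truth Truth table from [make_assembly()].
#' @param read_length Read length in bases (must not exceed the shortest
#'   contig).
#' @param seed Integer seed.
#' @param sam_path Output SAM path.
#' @return Invisibly, a list with `path`, `n_reads` and `aligned_bases`.
#' @export
make_alignments <- function(truth, read_length = 100L, seed = 0L, sam_path) {
  if (read_length > min(truth$length)) {
    stop("read_length exceeds shortest contig", call. = FALSE)
  }
  with_seed(seed, {
    header <- c("@HD\tVN:1.6\tSO:unknown",
                paste0("@SQ\tSN:", truth$id, "\tLN:", truth$length))
    records <- character(0)
    total_reads <- 0L
    for (i in seq_len(nrow(truth))) {
      n_reads <- as.integer(round(truth$cov[i] * truth$length[i] / read_length))
      if (n_reads == 0L) next
      pos <- 1L + floor(runif(n_reads) * (truth$length[i] - read_length + 1L))
      records <- c(records, paste0(
        truth$id[i], "_r", seq_len(n_reads), "\t0\t", truth$id[i], "\t",
        as.integer(pos), "\t60\t", read_length, "M\t*\t0\t0\t*\t*"))
      total_reads <- total_reads + n_reads
    }
    writeLines(c(header, records), sam_path)
    invisible(list(path = sam_path, n_reads = total_reads,
                   aligned_bases = total_reads * read_length))
  })
}

taxdump_leaves <- function(taxdump) {
  setdiff(names(taxdump$parent), taxdump$parent)
}

#' Generate per-database similarity-hit tables for a truth table
#'
#' Each contig selected at its component's hit rate receives 1-5 hits; a
#' fraction `hit_noise` of hits point to a different random leaf taxid.
#' Bitscores of true-taxid hits (uniform on [100, 200]) exceed noisy ones
#' (uniform on [20, 80]) in expectation. Output columns follow the
#' `qseqid staxids bitscore sseqid qstart qend` layout.
#'
#' @param truth Truth table from [make_assembly()].
#' @param taxdump A [read_taxdump()] taxonomy (noisy taxids are drawn from
#'   its leaves).
#' @param seed Integer seed.
#' @param n_dbs Number of database hit tables to emit.
#' @param out_paths Optional character vector of TSV paths, one per database.
#' @return List of hit data frames ([parse_tabular_hits()] layout), one per
#'   database.
#' @export
make_hits <- function(truth, taxdump, seed = 0L, n_dbs = 1L,
                      out_paths = NULL) {
  leaves <- as.integer(taxdump_leaves(taxdump))
  with_seed(seed, {
    dbs <- lapply(seq_len(n_dbs) - 1L, function(db) {
      rows <- list()
      for (i in seq_len(nrow(truth))) {
        if (runif(1) >= truth$hit_rate[i]) next
        n_hits <- sample.int(5L, 1L)
        for (h in seq_len(n_hits)) {
          noisy <- runif(1) < truth$hit_noise[i]
          taxid <- if (noisy) {
            sample(setdiff(leaves, truth$taxid[i]), 1L)
          } else {
            truth$taxid[i]
          }
          bitscore <- if (noisy) runif(1, 20, 80) else runif(1, 100, 200)
          qstart <- 1L + floor(runif(1) * (truth$length[i] - 50L))
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = truth$id[i], taxid = as.integer(taxid),
            bitscore = round(bitscore, 1), subject_id = paste0("subj_", taxid),
            qstart = as.integer(qstart), qend = as.integer(qstart + 49L),
            db_index = db, stringsAsFactors = FALSE)
        }
      }
      if (!length(rows)) {
        return(data.frame(query_id = character(0), taxid = integer(0),
                          bitscore = numeric(0), subject_id = character(0),
                          qstart = integer(0), qend = integer(0),
                          db_index = integer(0), stringsAsFactors = FALSE))
      }
      do.call(rbind, rows)
    })
    if (!is.null(out_paths)) {
      stopifnot(length(out_paths) == n_dbs)
      for (i in seq_len(n_dbs)) {
        h <- dbs[[i]]
        writeLines(paste(h$query_id, h$taxid, h$bitscore, h$subject_id,
                         h$qstart, h$qend, sep = "\t"), out_paths[i])
      }
    }
    dbs
  })
}

#' A miniature two-superkingdom taxonomy tree
#'
#' Host (Drosophila, Arthropoda) plus two bacterial phyla (Proteobacteria
#' with Acetobacter and Gluconobacter species, Firmicutes with a
#' Lactobacillus), every leaf with ancestors at all eight ranks.
#'
#' @return Data frame with columns `taxid`, `parent`, `rank`, `name`.
#' @export
example_tree <- function() {
  rbind(
    data.frame(taxid = 1L, parent = 1L, rank = "no rank", name = "root"),
    # Eukaryota -> Drosophila melanogaster
    data.frame(
      taxid = c(2759L, 33208L, 6656L, 50557L, 7147L, 7214L, 7215L, 7227L),
      parent = c(1L, 2759L, 33208L, 6656L, 50557L, 7147L, 7214L, 7215L),
      rank = blob_ranks(),
      name = c("Eukaryota", "Metazoa", "Arthropoda", "Insecta", "Diptera",
               "Drosophilidae", "Drosophila", "Drosophila melanogaster")),
    # Bacteria -> Proteobacteria -> Acetobacter / Gluconobacter
    data.frame(
      taxid = c(2L, 1000L, 1224L, 28211L, 204441L, 433L, 434L, 435L),
      parent = c(1L, 2L, 1000L, 1224L, 28211L, 204441L, 433L, 434L),
      rank = blob_ranks(),
      name = c("Bacteria", "Monera", "Proteobacteria", "Alphaproteobacteria",
               "Rhodospirillales", "Acetobacteraceae", "Acetobacter",
               "Acetobacter pomorum")),
    data.frame(taxid = c(442L, 443L), parent = c(433L, 442L),
               rank = c("genus", "species"),
               name = c("Gluconobacter", "Gluconobacter oxydans")),
    # Bacteria -> Firmicutes -> Lactobacillus
    data.frame(
      taxid = c(1239L, 91061L, 186826L, 33958L, 1578L, 1580L),
      parent = c(1000L, 1239L, 91061L, 186826L, 33958L, 1578L),
      rank = c("phylum", "class", "order", "family", "genus", "species"),
      name = c("Firmicutes", "Bacilli", "Lactobacillales",
               "Lactobacillaceae", "Lactobacillus", "Lactobacillus brevis")))
}

#' Write a miniature NCBI-style taxdump
#'
#' Emits `nodes.dmp` and `names.dmp` in the pipe-delimited dialect for a tree
#' specification. With `inject_cycle` the first species' parent is rewired to
#' itself-as-descendant, producing a taxonomy the lineage walker must reject.
#'
#' @param tree Data frame with `taxid`, `parent`, `rank`, `name`
#'   (default [example_tree()]).
#' @param dir Output directory.
#' @param inject_cycle Corrupt the tree with a parent cycle.
#' @return `dir`, invisibly.
#' @export
make_mini_taxdump <- function(tree = example_tree(), dir,
                              inject_cycle = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inject_cycle) {
    sp <- which(tree$rank == "species")[1L]
    ge <- which(tree$taxid == tree$parent[sp])
    tree$parent[ge] <- tree$taxid[sp]
  }
  writeLines(paste0(tree$taxid, "\t|\t", tree$parent, "\t|\t", tree$rank,
                    "\t|"),
             file.path(dir, "nodes.dmp"))
  writeLines(paste0(tree$taxid, "\t|\t", tree$name, "\t|\t\t|\t",
                    "scientific name", "\t|"),
             file.path(dir, "names.dmp"))
  invisible(dir)
}

#' Inject a single named violation into a copy of a BlobDir
#'
#' Corruption kinds: `truncate_values` (drop the last entry of a value
#' array), `bad_index` (set a category value to `length(keys)`),
#' `stale_range` (shift a variable field's metadata range off the observed
#' values) and `missing_file` (delete a field file). Each corrupted copy must
#' be flagged as invalid by [validate_blobdir()].
#'
#' @param path Source BlobDir.
#' @param kind Corruption kind.
#' @param out_path Destination directory for the mutated copy.
#' @return `out_path`, invisibly.
#' @export
corrupt_blobdir <- function(path,
                            kind = c("truncate_values", "bad_index",
                                     "stale_range", "missing_file"),
                            out_path) {
  kind <- match.arg(kind)
  dir.create(out_path, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(path, full.names = TRUE)) {
    file.copy(f, file.path(out_path, basename(f)), overwrite = TRUE)
  }
  meta <- read_json(file.path(out_path, "meta.json"), simplifyVector = FALSE)
  types <- vapply(meta$fields, function(m) as.character(m$type), character(1))
  ids <- vapply(meta$fields, function(m) as.character(m$id), character(1))
  pick <- function(type) {
    cand <- ids[types == type]
    if (!length(cand)) stop("no ", type, " field to corrupt", call. = FALSE)
    cand[[1L]]
  }
  rewrite <- function(fid, fun) {
    fpath <- file.path(out_path, paste0(fid, ".json"))
    doc <- read_json(fpath, simplifyVector = FALSE)
    write_json(fun(doc), fpath, auto_unbox = FALSE, digits = I(17))
  }
  if (kind == "truncate_values") {
    fid <- pick("variable")
    rewrite(fid, function(doc) {
      doc$values <- doc$values[-length(doc$values)]
      doc
    })
  } else if (kind == "bad_index") {
    fid <- pick("category")
    rewrite(fid, function(doc) {
      doc$values[[1L]] <- length(doc$keys)
      doc
    })
  } else if (kind == "stale_range") {
    fid <- pick("variable")
    i <- which(ids == fid)
    rng <- as.numeric(unlist(meta$fields[[i]]$range))
    meta$fields[[i]]$range <- if (rng[2] > rng[1]) {
      c(rng[1], rng[1] + (rng[2] - rng[1]) / 2)
    } else {
      c(rng[1] + 1, rng[2] + 2)
    }
    write_json(meta, file.path(out_path, "meta.json"), auto_unbox = TRUE,
               digits = I(17), null = "null", pretty = TRUE)
  } else {
    fid <- pick("variable")
    unlink(file.path(out_path, paste0(fid, ".json")))
  }
  invisible(out_path)
}
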