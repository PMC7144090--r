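# Shared fixtures and independent brute-force oracles.

tiny_dataset <- function(lengths = c(600, 400, 1500, 900),
                         gc = c(0.35, 0.36, 0.55, 0.34),
                         cov = c(30, 28, 5, 31),
                         phylum = c("Arthropoda", "Arthropoda",
                                    "Proteobacteria", "no-hit")) {
  n <- length(lengths)
  ids <- paste0("c", seq_len(n))
  ds <- create_dataset(ids, list(id = "tiny"))
  ds <- add_field(ds, blob_field("length", "variable", lengths,
                                 datatype = "integer"))
  ds <- add_field(ds, blob_field("gc", "variable", gc))
  ds <- add_field(ds, blob_field("cov", "variable", cov))
  keys <- sort(unique(phylum))
  ds <- add_field(ds, blob_field("phylum", "category",
                                 match(phylum, keys) - 1L, keys = keys))
  ds
}

fixture_taxdump <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "blobr-taxdump")
      make_mini_taxdump(dir = dir)
    }
    read_taxdump(dir)
  }
})

write_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

write_sam <- function(contigs, records, path = tempfile(fileext = ".sam")) {
  # contigs: named lengths; records: character vector of alignment lines
  writeLines(c("@HD\tVN:1.6",
               paste0("@SQ\tSN:", names(contigs), "\tLN:", contigs),
               records), path)
  path
}

sam_record <- function(qname, rname, pos, cigar, flag = 0L, mapq = 60L) {
  paste(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, "*", "*", sep = "\t")
}

write_busco_table <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("# BUSCO results", "# busco_id\tstatus\tcontig\tstart\tend",
               rows), path)
  path
}

# brute-force per-taxon bitscore accumulator: independent of apply_taxrule
oracle_taxrule <- function(hit_sets, taxdump, identifiers, taxrule,
                           ranks = blob_ranks()) {
  if (is.data.frame(hit_sets)) hit_sets <- list(hit_sets)
  out <- list()
  for (r in ranks) {
    taxon <- character(0)
    score <- numeric(0)
    cindex <- integer(0)
    for (id in identifiers) {
      per_db <- lapply(hit_sets, function(h) h[h$query_id == id, , drop = FALSE])
      hits <- if (taxrule == "bestsum") {
        do.call(rbind, per_db)
      } else {
        nonempty <- which(vapply(per_db, nrow, integer(1)) > 0L)
        if (length(nonempty)) per_db[[nonempty[1L]]] else per_db[[1L]][0, ]
      }
      if (!nrow(hits)) {
        taxon[id] <- "no-hit"
        score[id] <- 0
        cindex[id] <- 0L
        next
      }
      sums <- new.env()
      for (i in seq_len(nrow(hits))) {
        nm <- lineage_at_ranks(hits$taxid[i], taxdump, r)[[1]]
        prev <- if (exists(nm, sums)) get(nm, sums) else 0
        assign(nm, prev + hits$bitscore[i], sums)
      }
      taxa <- sort(ls(sums))
      vals <- vapply(taxa, get, numeric(1), envir = sums)
      best <- taxa[vals == max(vals)][1L]  # taxa sorted: lexicographic tie-break
      taxon[id] <- best
      score[id] <- max(vals)
      cindex[id] <- sum(vals > 0) - 1L
    }
    out[[r]] <- list(taxon = unname(taxon), score = unname(score),
                     cindex = unname(cindex))
  }
  out
}

random_hit_sets <- function(seed, identifiers, taxids, n_dbs = 2L) {
  set.seed(seed)
  lapply(seq_len(n_dbs) - 1L, function(db) {
    rows <- list()
    for (id in identifiers) {
      for (h in seq_len(sample(0:4, 1))) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = id, taxid = sample(taxids, 1L),
          bitscore = round(runif(1, 10, 300), 1),
          subject_id = "s", qstart = 1L, qend = 50L,
          db_index = db, stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) {
      return(data.frame(query_id = character(0), taxid = integer(0),
                        bitscore = numeric(0), subject_id = character(0),
                        qstart = integer(0), qend = integer(0),
                        db_index = integer(0)))
    }
    do.call(rbind, rows)
  })
}

# loop-based weighted moment oracles
oracle_wmean <- function(v, w) {
  s <- 0
  for (i in seq_along(v)) s <- s + w[i] * v[i]
  s / sum(w)
}
oracle_wsd <- function(v, w) {
  mu <- oracle_wmean(v, w)
  s <- 0
  for (i in seq_along(v)) s <- s + w[i] * (v[i] - mu)^2
  sqrt(s / sum(w))
}
oracle_wmedian <- function(v, w) {
  o <- order(v)
  cum <- 0
  for (i in o) {
    cum <- cum + w[i]
    if (cum >= sum(w) / 2) return(v[i])
  }
}
oracle_wslope <- function(x, y, w) {
  mx <- oracle_wmean(x, w)
  my <- oracle_wmean(y, w)
  num <- 0
  den <- 0
  for (i in seq_along(x)) {
    num <- num + w[i] * (x[i] - mx) * (y[i] - my)
    den <- den + w[i] * (x[i] - mx)^2
  }
  if (den == 0) 0 else num / den
}
oracle_nx <- function(lengths, fraction) {
  l <- sort(lengths, decreasing = TRUE)
  total <- sum(l)
  cum <- 0
  for (x in l) {
    cum <- cum + x
    if (cum >= fraction * total) return(x)
  }
}

# aligned bases counted straight off the SAM text (primary mapped records)
sam_aligned_bases <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  total <- 0
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L || bitwAnd(flag, 256L) > 0L ||
        bitwAnd(flag, 2048L) > 0L) next
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", f[6])[[1]]
    for (tok in regmatches(f[6], gregexpr("[0-9]+[MIDNSHP=X]", f[6]))[[1]]) {
      op <- substr(tok, nchar(tok), nchar(tok))
      if (op %in% c("M", "=", "X")) {
        total <- total + as.numeric(substr(tok, 1, nchar(tok) - 1))
      }
    }
  }
  total
}
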