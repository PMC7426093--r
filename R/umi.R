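#' Discard reads whose UMI contains an undetermined base
#'
#' Removes every record whose UMI carries an `N`; all other records pass
#' through untouched.
#'
#' @param reads data.frame with columns `barcode`, `gene`, `umi`, `reads`.
#' @return the filtered read table.
#' @export
drop_n_umis <- function(reads) {
  check_read_table(reads)
  reads[!grepl("N", reads$umi, fixed = TRUE), , drop = FALSE]
}

check_read_table <- function(reads) {
  need <- c("barcode", "gene", "umi", "reads")
  if (!all(need %in% names(reads))) {
    stop_format("read table must have columns %s",
                paste(need, collapse = ", "))
  }
  if (any(reads$reads < 1)) stop_format("read counts must be >= 1")
  invisible(reads)
}

#' Collapse singleton UMIs arising from sequencing errors
#'
#' Within each (barcode, gene) group, a UMI observed by exactly one read
#' that lies at hamming distance 1 from a UMI supported by two or more
#' reads is treated as a sequencing error of that neighbor: its read is
#' added to the neighbor and the singleton is removed. UMIs with two or
#' more reads are never merged away, and singleton pairs never merge into
#' each other. When a singleton has several qualifying neighbors, the one
#' with the most reads wins, ties going to the lexicographically smallest
#' UMI. The pass is single and works from the initial table state: reads
#' gained during the pass do not recruit further singletons. Total reads
#' are conserved.
#'
#' @param reads read table (N-containing UMIs should already be removed,
#'   see [drop_n_umis()]).
#' @return the collapsed read table, sorted by barcode, gene, UMI.
#' @export
collapse_umis <- function(reads) {
  check_read_table(reads)
  if (nrow(reads) == 0L) return(reads)
  lens <- unique(nchar(reads$umi))
  if (length(lens) != 1L) {
    stop_format("inconsistent UMI lengths in read table: %s",
                paste(sort(lens), collapse = ", "))
  }
  L <- lens
  dt <- data.table::as.data.table(reads)
  rec <- dt[dt$reads >= 2L]
  sing <- dt[dt$reads == 1L]
  gained <- NULL
  if (nrow(rec) > 0L && nrow(sing) > 0L) {
    sing[, "sid" := seq_len(nrow(sing))]
    vars <- vector("list", 3L * L)
    i <- 0L
    for (p in seq_len(L)) {
      cur <- substr(sing$umi, p, p)
      for (b in c("A", "C", "G", "T")) {
        sel <- cur != b
        if (!any(sel)) next
        v <- sing$umi[sel]
        substr(v, p, p) <- b
        i <- i + 1L
        vars[[i]] <- data.table::data.table(sid = sing$sid[sel],
                                            barcode = sing$barcode[sel],
                                            gene = sing$gene[sel],
                                            umi = v)
      }
    }
    vars <- data.table::rbindlist(vars[seq_len(i)])
    hits <- rec[vars, on = c("barcode", "gene", "umi"), nomatch = NULL]
    if (nrow(hits) > 0L) {
      data.table::setorderv(hits, c("sid", "reads", "umi"),
                            order = c(1L, -1L, 1L))
      best <- hits[!duplicated(hits$sid)]
      gained <- best[, list(gain = .N),
                     by = c("barcode", "gene", "umi")]
      sing <- sing[!sing$sid %in% best$sid]
    }
    sing[, "sid" := NULL]
  }
  if (!is.null(gained)) {
    rec <- merge(rec, gained, by = c("barcode", "gene", "umi"),
                 all.x = TRUE)
    rec[is.na(rec$gain), "gain" := 0L]
    rec[, "reads" := rec$reads + rec$gain]
    rec[, "gain" := NULL]
  }
  out <- data.table::rbindlist(list(rec, sing), use.names = TRUE)
  data.table::setorderv(out, c("barcode", "gene", "umi"))
  as.data.frame(out)
}

#' Count distinct UMIs per (barcode, gene)
#'
#' Builds the genes x barcodes molecule-count matrix from a (collapsed)
#' read table: each entry is the number of distinct UMIs observed for that
#' barcode and gene.
#'
#' @param reads read table.
#' @param genes,barcodes optional identifier vectors fixing the matrix
#'   dimensions (useful to retain all-zero rows/columns); default to the
#'   identifiers present in the table.
#' @return sparse integer matrix, genes x barcodes.
#' @export
reads_to_counts <- function(reads, genes = NULL, barcodes = NULL) {
  check_read_table(reads)
  genes <- genes %||% sort(unique(reads$gene))
  barcodes <- barcodes %||% sort(unique(reads$barcode))
  if (nrow(reads) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(genes), length(barcodes)),
                                dimnames = list(genes, barcodes)))
  }
  gi <- match(reads$gene, genes)
  bi <- match(reads$barcode, barcodes)
  if (anyNA(gi) || anyNA(bi)) {
    stop_format("read table contains genes/barcodes absent from the supplied universe")
  }
  m <- Matrix::sparseMatrix(i = gi, j = bi, x = 1,
                            dims = c(length(genes), length(barcodes)),
                            dimnames = list(genes, barcodes))
  m
}

#' Read / write a read-level table as TSV
#'
#' Plain TSV with header `barcode gene umi reads`.
#' @param path file path.
#' @return for the reader, the read table data.frame.
#' @export
read_read_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1:3, integer = 4))
  check_read_table(as.data.frame(dt))
}

#' @rdname read_read_table
#' @param reads read table to write.
#' @export
write_read_table <- function(reads, path) {
  check_read_table(reads)
  data.table::fwrite(reads, path, sep = "\t")
  invisible(path)
}
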