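# Readers and writers for the external formats the pipeline touches.
# Coordinates are 1-based inclusive throughout, the native convention of
# GFF3 and of the Bioconductor containers used here.

#' Read a FASTA file
#'
#' @param path file path.
#' @param alphabet `"protein"` or `"dna"`; controls validation only, residues
#'   are returned upper-cased either way.
#' @return tibble with columns `id`, `description`, `seq`, `alphabet`, in file
#'   order. An empty file yields an empty tibble.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(id = character(), description = character(),
                          seq = character(), alphabet = character()))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) {
    stop("malformed FASTA: line 1 is not a header line")
  }
  bad <- which(!is_hdr & grepl("[^A-Za-z*.\\-]", lines))
  if (length(bad)) stop("malformed FASTA sequence at line ", bad[1])
  grp <- cumsum(is_hdr)
  hdr <- sub("^>", "", lines[is_hdr])
  id <- sub("\\s.*$", "", hdr)
  if (any(id == "")) {
    stop("malformed FASTA header at line ", which(is_hdr)[id == ""][1])
  }
  if (anyDuplicated(id)) stop("duplicate FASTA ids: ", id[duplicated(id)][1])
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  seq_out <- character(length(id))
  names(seq_out) <- as.character(seq_along(id))
  seq_out[names(seqs)] <- seqs
  tibble::tibble(id = id, description = desc, seq = unname(seq_out),
                 alphabet = alphabet)
}

#' Write sequences to FASTA
#'
#' @param records tibble with `id`, `seq` and optionally `description`.
#' @param path output path. @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    desc <- if ("description" %in% names(records) &&
                nzchar(records$description[i]))
      paste0(" ", records$description[i]) else ""
    writeLines(paste0(">", records$id[i], desc), con)
    s <- records$seq[i]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' One gene model per mRNA feature. Exon and CDS spans are kept 1-based
#' inclusive and sorted; CDS spans must fall inside the exon union.
#'
#' @param path GFF3 file with gene/mRNA/exon/CDS features.
#' @return tibble with columns `gene_id`, `mrna_id`, `protein_id`, `seqid`,
#'   `strand`, and list-columns `exons`, `cds` (two-column matrices
#'   `start`,`end`).
#' @export
read_gff3 <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  mrna <- df[df$type == "mRNA", ]
  get1 <- function(x) vapply(x, function(v) if (length(v)) as.character(v[1]) else NA_character_, character(1))
  models <- purrr::map(seq_len(nrow(mrna)), function(i) {
    mid <- as.character(mrna$ID[i])
    kids <- df[!is.na(get1(df$Parent)) & get1(df$Parent) == mid, ]
    ex <- kids[kids$type == "exon", c("start", "end")]
    cds <- kids[kids$type == "CDS", c("start", "end")]
    ex <- as.matrix(ex[order(ex$start), , drop = FALSE])
    cds <- as.matrix(cds[order(cds$start), , drop = FALSE])
    # validation: every CDS interval inside some exon
    if (nrow(cds)) {
      inside <- vapply(seq_len(nrow(cds)), function(k) {
        any(ex[, 1] <= cds[k, 1] & cds[k, 2] <= ex[, 2])
      }, logical(1))
      if (!all(inside)) {
        stop("CDS outside exon bounds for gene ",
             get1(mrna$Parent)[i] %||% mid)
      }
    }
    prot <- if ("protein_id" %in% names(mrna)) as.character(mrna$protein_id[i]) else NA_character_
    tibble::tibble(
      gene_id = get1(mrna$Parent)[i] %||% mid,
      mrna_id = mid,
      protein_id = prot %||% NA_character_,
      seqid = as.character(mrna$seqnames[i]),
      strand = as.character(mrna$strand[i]),
      exons = list(ex), cds = list(cds))
  })
  dplyr::bind_rows(models)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

#' Write gene models to GFF3
#'
#' @param models tibble as returned by [read_gff3()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    ex <- g$exons[[1]]; cds <- g$cds[[1]]
    span <- range(c(ex, cds))
    line <- function(type, s, e, attrs) {
      sprintf("%s\tnlrscan\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              g$seqid, type, s, e, g$strand,
              if (type == "CDS") "0" else ".", attrs)
    }
    writeLines(line("gene", span[1], span[2],
                    sprintf("ID=%s", g$gene_id)), con)
    writeLines(line("mRNA", span[1], span[2],
                    sprintf("ID=%s;Parent=%s;protein_id=%s",
                            g$mrna_id, g$gene_id, g$protein_id)), con)
    for (k in seq_len(nrow(ex))) {
      writeLines(line("exon", ex[k, 1], ex[k, 2],
                      sprintf("Parent=%s", g$mrna_id)), con)
    }
    for (k in seq_len(nrow(cds))) {
      writeLines(line("CDS", cds[k, 1], cds[k, 2],
                      sprintf("Parent=%s", g$mrna_id)), con)
    }
  }
  invisible(path)
}

#' Spliced CDS of a gene model
#'
#' Concatenates the CDS intervals on the genomic strand and
#' reverse-complements for minus-strand genes.
#'
#' @param model one-row gene-model tibble.
#' @param scaffold_seq character scalar, the scaffold DNA.
#' @return character scalar CDS (5' to 3' of the mRNA).
#' @export
spliced_cds <- function(model, scaffold_seq) {
  cds <- model$cds[[1]]
  pieces <- substring(scaffold_seq, cds[, 1], cds[, 2])
  s <- paste(pieces, collapse = "")
  if (model$strand == "-") s <- revcomp(s)
  s
}

#' Read a scaffold anchoring table
#'
#' Tab-separated columns: `scaffold_id`, `chromosome`, `chromosome_offset`
#' (bases preceding the scaffold on the pseudomolecule), `orientation`
#' (`+`/`-`), `scaffold_length`.
#'
#' @param path TSV path.
#' @return tibble.
#' @export
read_anchor_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("scaffold_id", "chromosome", "chromosome_offset", "orientation",
            "scaffold_length")
  stopifnot(all(need %in% names(df)))
  stopifnot(all(df$chromosome_offset >= 0), !anyDuplicated(df$scaffold_id))
  tibble::as_tibble(df[need])
}

#' @rdname read_anchor_table
#' @param anchor anchor-table tibble.
#' @export
write_anchor_table <- function(anchor, path) {
  utils::write.table(anchor, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Stockholm alignment
#'
#' @param path Stockholm (1.0) file.
#' @return tibble with columns `id`, `seq`; rows have uniform length, gaps
#'   as `-`.
#' @export
read_stockholm <- function(path) {
  aln <- Biostrings::readAAMultipleAlignment(path, format = "stockholm")
  m <- as.character(aln)
  tibble::tibble(id = names(m), seq = toupper(gsub("\\.", "-", unname(m))))
}

#' @rdname read_stockholm
#' @param aln tibble with `id`, `seq`.
#' @export
write_stockholm <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  wid <- max(nchar(aln$id)) + 2
  writeLines(sprintf(paste0("%-", wid, "s%s"), aln$id, aln$seq), con)
  writeLines("//", con)
  invisible(path)
}

#' Write a phylogenetic tree to Newick
#'
#' Branch lengths are written with full precision and bootstrap supports (if
#' present in `node.label`) as internal node labels; leaf names containing
#' whitespace are quoted.
#'
#' @param tree an `ape::phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  tr <- tree
  lab <- gsub("^'|'$", "", tr$tip.label)
  ws <- grepl("[[:space:]]", lab)
  tr$tip.label <- ifelse(ws, gsub(" ", "\x01", lab), lab)
  txt <- ape::write.tree(tr, digits = 10)
  for (l in lab[ws]) {
    txt <- gsub(gsub(" ", "\x01", l, fixed = TRUE),
                paste0("'", l, "'"), txt, fixed = TRUE)
  }
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  tr$tip.label <- gsub("^'|'$", "", tr$tip.label)
  tr
}

#' Write intervals as BED
#'
#' BED is 0-based half-open on disk; the 1-based inclusive columns given here
#' are converted at the boundary.
#'
#' @param df tibble with `seqid`, `start`, `end` (1-based inclusive) and
#'   optionally `name`, `score`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(df$seqid, df$start - 1L, df$end,
                    if ("name" %in% names(df)) df$name else ".",
                    if ("score" %in% names(df)) df$score else 0,
                    if ("strand" %in% names(df)) df$strand else ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
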