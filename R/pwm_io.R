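#' Read position weight matrices from a motif file
#'
#' Supports TRANSFAC-style matrix blocks (`ID`/`P0`/numbered position rows,
#' records separated by `//`) and JASPAR files (a `>id name` header followed
#' by four base rows `A [ ... ]` ... `T [ ... ]`, or four bare numeric
#' rows). Count matrices are converted to probabilities column-wise with an
#' additive pseudocount per base.
#'
#' @param path Path to the motif file.
#' @param format `"transfac"` or `"jaspar"`.
#' @param pseudocount Additive pseudocount per base applied to count
#'   matrices before normalization; default 0.01. Matrices whose columns
#'   already sum to 1 are also smoothed with the same pseudocount for
#'   consistency (set `pseudocount = 0` to disable).
#' @return List of [pwm] objects, in file order.
#' @export
read_pwms <- function(path, format = c("transfac", "jaspar"),
                      pseudocount = 0.01) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("motif file is empty: ", path)
  pwms <- switch(format,
                 transfac = parse_transfac(lines, pseudocount),
                 jaspar = parse_jaspar(lines, pseudocount))
  if (length(pwms) == 0L) stop("no motif records found in ", path)
  ids <- vapply(pwms, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate PWM ids: ", paste(unique(ids[duplicated(ids)]),
                                      collapse = ", "))
  pwms
}

parse_transfac <- function(lines, pseudocount) {
  recs <- split(lines, cumsum(grepl("^//", lines)))
  out <- list()
  for (rec in recs) {
    rec <- rec[!grepl("^//", rec)]
    if (length(rec) == 0L) next
    id_line <- grep("^(ID|NA|AC)\\s+", rec, value = TRUE)
    if (length(id_line) == 0L) next
    id <- strsplit(trimws(id_line[grepl("^(ID|AC)", id_line)][1]
                          %||% id_line[1]), "\\s+")[[1]][2]
    tf <- NULL
    na_line <- grep("^NA\\s+", rec, value = TRUE)
    if (length(na_line) > 0L)
      tf <- sub("^NA\\s+", "", na_line[1])
    pos_rows <- grep("^\\s*[0-9]+\\s+[-0-9.eE]", rec, value = TRUE)
    if (length(pos_rows) == 0L)
      stop("TRANSFAC record '", id, "': no position rows found")
    vals <- lapply(pos_rows, function(l) {
      f <- strsplit(trimws(l), "\\s+")[[1]]
      suppressWarnings(as.numeric(f[2:min(5, length(f))]))
    })
    nv <- lengths(vals)
    if (any(nv != 4L) || anyNA(unlist(vals)))
      stop("TRANSFAC record '", id,
           "': each position row must carry 4 numeric values (A C G T)")
    m <- t(do.call(rbind, vals))  # 4 x L, rows A,C,G,T
    out[[length(out) + 1L]] <- finish_pwm(id, m, tf, pseudocount)
  }
  out
}

parse_jaspar <- function(lines, pseudocount) {
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L)
    stop("JASPAR file has no '>' headers")
  bounds <- c(hdr, length(lines) + 1L)
  out <- vector("list", length(hdr))
  for (k in seq_along(hdr)) {
    head_fields <- strsplit(sub("^>\\s*", "", lines[hdr[k]]), "\\s+")[[1]]
    id <- head_fields[1]
    tf <- if (length(head_fields) > 1L)
      paste(head_fields[-1], collapse = " ") else NULL
    body <- lines[seq(hdr[k] + 1L, bounds[k + 1L] - 1L)]
    body <- body[!grepl("^>", body)]
    if (length(body) != 4L)
      stop("JASPAR record '", id, "': expected 4 matrix rows, got ",
           length(body))
    rows <- lapply(body, function(l) {
      l2 <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l2 <- gsub("[][]", " ", l2)
      suppressWarnings(as.numeric(strsplit(trimws(l2), "\\s+")[[1]]))
    })
    if (anyNA(unlist(rows)))
      stop("JASPAR record '", id, "': non-numeric matrix entries")
    if (length(unique(lengths(rows))) != 1L)
      stop("JASPAR record '", id, "': matrix rows have unequal lengths")
    base_order <- vapply(body, function(l)
      toupper(substr(trimws(l), 1, 1)), "")
    m <- do.call(rbind, rows)
    if (all(sort(base_order) == DNA_BASES)) {
      m <- m[match(DNA_BASES, base_order), , drop = FALSE]
    }
    out[[k]] <- finish_pwm(id, m, tf, pseudocount)
  }
  out
}

finish_pwm <- function(id, m, tf, pseudocount) {
  # frequency matrices (columns ~1) and count matrices get the same
  # pseudocount smoothing; for frequencies this is a no-op at pseudocount 0
  pwm(id, m, tf_label = tf, counts = TRUE, pseudocount = pseudocount)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L ||
                             (length(a) == 1L && is.na(a))) b else a

#' Write PWMs to a motif file
#'
#' @param pwms List of [pwm] objects.
#' @param path Output path.
#' @param format `"transfac"` or `"jaspar"`. Probabilities are written (not
#'   counts).
#' @return `path`, invisibly.
#' @export
write_pwms <- function(pwms, path, format = c("transfac", "jaspar")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    validate_pwm(p)
    if (format == "transfac") {
      writeLines(c(paste("ID", p$id),
                   if (!is.null(p$tf_label)) paste("NA", p$tf_label),
                   "P0\tA\tC\tG\tT"), con)
      for (j in seq_len(p$length))
        writeLines(paste(c(sprintf("%02d", j),
                           format(p$matrix[, j], digits = 6)),
                         collapse = "\t"), con)
      writeLines("//", con)
    } else {
      writeLines(paste0(">", p$id,
                        if (!is.null(p$tf_label)) paste0(" ", p$tf_label)),
                 con)
      for (b in seq_len(4L))
        writeLines(paste0(DNA_BASES[b], " [ ",
                          paste(format(p$matrix[b, ], digits = 6),
                                collapse = " "), " ]"), con)
    }
  }
  invisible(path)
}

#' Read DNA sequences from a FASTA file
#'
#' Sequences are upper-cased and restricted to the alphabet \{A,C,G,T,N\}.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are record ids, the
#'   first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("FASTA file has no records: ", path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence(s) contain characters outside {A,C,G,T,N}: ",
         paste(ids[bad], collapse = ", "))
  names(seqs) <- ids
  seqs
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width; default 70.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  ss <- Biostrings::DNAStringSet(toupper(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
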