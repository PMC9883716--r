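#' Read sequences from a FASTA file
#'
#' Record IDs are the first whitespace-delimited token of each header;
#' letters are folded to upper case and line wrapping is ignored.
#'
#' @param path FASTA file (one or more records).
#' @param alphabet if non-NULL, validate every letter against it, with an
#'   error naming the first offending record and position.  Defaults to the
#'   DNA alphabet; pass `NULL` to skip validation (e.g. protein input).
#' @return Named character vector of sequences.
#' @export
parse_fasta <- function(path, alphabet = c("A", "C", "G", "T")) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA record ID: ", ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (!is.null(alphabet)) {
    for (k in seq_along(seqs)) {
      letters_k <- strsplit(seqs[[k]], "")[[1L]]
      bad <- which(!(letters_k %in% toupper(alphabet)))
      if (length(bad))
        stop(sprintf(
          "illegal character '%s' at position %d of record '%s'",
          letters_k[bad[1L]], bad[1L], ids[k]))
    }
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a substitution score matrix
#'
#' Accepts a built-in name (`"HoxD70"`, `"Simple"`) or a path to an
#' NCBI-style matrix file: '#' comment lines, then a line of
#' whitespace-separated alphabet letters, then one line per reference letter
#' of the form "letter score score ...".
#'
#' @param x built-in name or file path.
#' @return Numeric matrix with alphabet dimnames.
#' @export
parse_matrix <- function(x) {
  if (x %in% c("HoxD70", "Simple")) return(builtin_matrix(x))
  lines <- readLines(x)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("matrix file has no data: ", x)
  alphabet <- strsplit(lines[1L], "[ \t]+")[[1L]]
  if (anyDuplicated(alphabet)) stop("duplicate letter in matrix header")
  k <- length(alphabet)
  rows <- strsplit(lines[-1L], "[ \t]+")
  if (length(rows) != k)
    stop("expected ", k, " matrix rows, found ", length(rows))
  row_letters <- vapply(rows, `[`, "", 1L)
  if (anyDuplicated(row_letters)) stop("duplicate row letter in matrix")
  if (!setequal(row_letters, alphabet))
    stop("matrix row letters do not match the header alphabet")
  S <- matrix(NA_real_, k, k, dimnames = list(alphabet, alphabet))
  for (r in rows) {
    if (length(r) != k + 1L)
      stop("ragged matrix row for letter '", r[1L], "'")
    vals <- suppressWarnings(as.numeric(r[-1L]))
    if (anyNA(vals))
      stop("non-numeric cell in matrix row for letter '", r[1L], "'")
    S[r[1L], ] <- vals
  }
  S
}

#' Write a substitution score matrix
#'
#' @param S numeric matrix with alphabet dimnames.
#' @param path output path.
#' @param comment optional comment written as a '#' header line.
#' @export
write_matrix <- function(S, path, comment = NULL) {
  lines <- character(0)
  if (!is.null(comment)) lines <- paste("#", comment)
  lines <- c(lines, paste(colnames(S), collapse = " "))
  for (i in seq_len(nrow(S)))
    lines <- c(lines, paste(c(rownames(S)[i],
                              sprintf("%.17g", S[i, ])), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write pair-HMM parameters to a key-value file
#'
#' Flat "name value" lines: `topology`, `alphabet` (space-separated
#' letters), `phi_<x>`, `psi_<y>`, `pi_<x>_<y>`, and the transition
#' probabilities.  Floats are written with 17 significant digits so that
#' reading the file back reproduces them exactly.
#'
#' @param params a `"phmm_params"` object.
#' @param path output path.
#' @export
write_phmm_params <- function(params, path) {
  stopifnot(inherits(params, "phmm_params"))
  al <- params$alphabet
  lines <- c(paste("topology", params$topology),
             paste("alphabet", paste(al, collapse = " ")))
  for (x in seq_along(al))
    lines <- c(lines, paste("phi", al[x], fmt_num(params$phi[x])),
               paste("psi", al[x], fmt_num(params$psi[x])))
  for (x in seq_along(al)) for (y in seq_along(al))
    lines <- c(lines, paste0("pi_", al[x], "_", al[y], " ",
                             fmt_num(params$pi[x, y])))
  for (nm in c("omega_D", "omega_I", "gamma", "alpha_D", "beta_D",
               "alpha_I", "beta_I", "t"))
    if (!is.na(params[[nm]]))
      lines <- c(lines, paste(nm, fmt_num(params[[nm]])))
  writeLines(lines, path)
  invisible(path)
}

#' Read pair-HMM parameters from a key-value file
#'
#' @param path file written by [write_phmm_params()].
#' @return A `"phmm_params"` object.
#' @export
read_phmm_params <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[ \t]+")
  key1 <- vapply(toks, `[`, "", 1L)
  get1 <- function(k, default = NA_real_) {
    i <- which(key1 == k)
    if (!length(i)) return(default)
    as.numeric(toks[[i[1L]]][2L])
  }
  topology <- toks[[which(key1 == "topology")[1L]]][2L]
  al <- toks[[which(key1 == "alphabet")[1L]]][-1L]
  k <- length(al)
  phi <- psi <- stats::setNames(numeric(k), al)
  for (i in which(key1 == "phi")) phi[toks[[i]][2L]] <-
      as.numeric(toks[[i]][3L])
  for (i in which(key1 == "psi")) psi[toks[[i]][2L]] <-
      as.numeric(toks[[i]][3L])
  pi <- matrix(NA_real_, k, k, dimnames = list(al, al))
  for (x in al) for (y in al)
    pi[x, y] <- get1(paste0("pi_", x, "_", y))
  phmm_params(topology, phi, psi, pi,
              omega_D = get1("omega_D"), omega_I = get1("omega_I"),
              gamma = get1("gamma"),
              alpha_D = get1("alpha_D"), beta_D = get1("beta_D"),
              alpha_I = get1("alpha_I"), beta_I = get1("beta_I"),
              t = get1("t"))
}

## reliability value -> one display character: '0'..'9' for [k/10, (k+1)/10),
## '+' for values >= 0.995
prob_char <- function(p) {
  ifelse(p >= 0.995, "+", as.character(pmin(9L, floor(p * 10))))
}

#' Render an alignment as a MAF block with a column-reliability line
#'
#' Produces the standard MAF 'a'/'s' lines plus a 'p' line encoding each
#' column's reliability as one character: digits 0-9 for probability bins
#' of width 0.1, '+' for 0.995 and above.
#'
#' @param aln a `"local_alignment"`.
#' @param reliabilities per-column reliabilities from
#'   [column_reliability()].
#' @param r_id,q_id sequence names.
#' @param r_size,q_size full source sequence lengths.
#' @return Character vector of MAF lines (empty for an empty alignment).
#' @export
write_posterior_maf <- function(aln, reliabilities, r_id, q_id,
                                r_size, q_size) {
  stopifnot(inherits(aln, "local_alignment"))
  if (length(aln$ops) == 0L) return(character(0))
  if (length(reliabilities) != length(aln$ops))
    stop("one reliability per alignment column is required")
  w <- max(nchar(c(r_id, q_id)))
  s_line <- function(id, start, len, size, text)
    sprintf("s %-*s %6d %6d + %6d %s", w, id, start, len, size, text)
  c(sprintf("a score=%s", format(aln$score)),
    s_line(r_id, aln$r_start, aln$r_end - aln$r_start, r_size, aln$r_row),
    s_line(q_id, aln$q_start, aln$q_end - aln$q_start, q_size, aln$q_row),
    sprintf("p %-*s %6s %6s   %6s %s", w, "", "", "", "",
            paste(prob_char(reliabilities), collapse = "")))
}

#' Generate a deterministic test sequence pair
#'
#' Seeded generator for sequence pairs with controlled structure:
#' `"identity"` (Q is a copy of R), `"diverged"` (independent substitutions
#' at the given rate, no indels), `"repeat"` (Q carries a tandem duplication
#' of a segment of R), `"random"` (independent sequences).
#'
#' @param kind one of `"identity"`, `"diverged"`, `"repeat"`, `"random"`.
#' @param length sequence length.
#' @param divergence substitution probability per site (diverged kind).
#' @param seed integer seed.
#' @param alphabet letters to draw from.
#' @return list with character strings `R` and `Q`.
#' @export
make_fixture <- function(kind = c("identity", "diverged", "repeat",
                                  "random"),
                         length, divergence = 0, seed,
                         alphabet = c("A", "C", "G", "T")) {
  kind <- match.arg(kind)
  stopifnot(divergence >= 0, divergence <= 1, length >= 1)
  with_rng(seed, {
    r <- sample(alphabet, length, replace = TRUE)
    q <- switch(kind,
      identity = r,
      random = sample(alphabet, length, replace = TRUE),
      diverged = {
        hit <- stats::runif(length) < divergence
        q <- r
        ## substitute to a uniformly chosen *different* letter
        q[hit] <- vapply(r[hit], function(x)
          sample(setdiff(alphabet, x), 1L), "")
        q
      },
      `repeat` = {
        span <- max(2L, min(length %/% 3L, 20L))
        at <- sample.int(length - span + 1L, 1L)
        seg <- r[at:(at + span - 1L)]
        append(r, seg, after = at + span - 1L)
      })
    list(R = paste(r, collapse = ""), Q = paste(q, collapse = ""))
  })
}
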