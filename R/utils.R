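# Internal helpers shared across the pipeline.
#
# All genomic coordinates inside the package are 0-based half-open [start,
# end); conversion to/from the 1-based closed convention happens only at the
# GFF/BAM boundaries.

`%||%` <- function(a, b) if (is.null(a)) b else a

tei_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[teiscan] ", ...)
}

## strict half-open interval overlap: [lo1,hi1) vs [lo2,hi2)
ivl_overlaps <- function(lo1, hi1, lo2, hi2) {
  lo1 < hi2 & lo2 < hi1
}

## 0-based half-open -> IRanges (1-based closed)
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# CIGAR parsing ---------------------------------------------------------

## ops consuming reference / query
.CIG_REF <- c("M", "D", "N", "=", "X")
.CIG_QRY <- c("M", "I", "S", "=", "X")

.parse_cigar_one <- function(cig) {
  if (is.na(cig) || cig == "*") {
    return(c(ref = 0L, qry = 0L, lclip = 0L, rclip = 0L))
  }
  m <- gregexpr("\\d+[MIDNSHP=X]", cig)[[1]]
  toks <- regmatches(cig, list(m))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", toks))
  op <- substr(toks, nchar(toks), nchar(toks))
  lclip <- if (op[1] == "S") n[1] else 0L
  k <- length(op)
  rclip <- if (k > 1L && op[k] == "S") n[k] else 0L
  c(ref = sum(n[op %in% .CIG_REF]), qry = sum(n[op %in% .CIG_QRY]),
    lclip = lclip, rclip = rclip)
}

## Vectorised CIGAR summary with fast paths for the overwhelmingly common
## shapes (kM, kSkM, kMkS); returns data.frame(ref_width, qwidth, lclip,
## rclip).
parse_cigar <- function(cigar) {
  n <- length(cigar)
  ref <- integer(n); qry <- integer(n)
  lclip <- integer(n); rclip <- integer(n)
  done <- logical(n)

  simple <- grepl("^\\d+M$", cigar)
  if (any(simple)) {
    w <- as.integer(sub("M$", "", cigar[simple]))
    ref[simple] <- w; qry[simple] <- w
    done[simple] <- TRUE
  }
  lm <- !done & grepl("^\\d+S\\d+M$", cigar)
  if (any(lm)) {
    s <- as.integer(sub("S.*$", "", cigar[lm]))
    w <- as.integer(sub("^\\d+S", "", sub("M$", "", cigar[lm])))
    ref[lm] <- w; qry[lm] <- s + w; lclip[lm] <- s
    done[lm] <- TRUE
  }
  rm_ <- !done & grepl("^\\d+M\\d+S$", cigar)
  if (any(rm_)) {
    w <- as.integer(sub("M.*$", "", cigar[rm_]))
    s <- as.integer(sub("S$", "", sub("^\\d+M", "", cigar[rm_])))
    ref[rm_] <- w; qry[rm_] <- w + s; rclip[rm_] <- s
    done[rm_] <- TRUE
  }
  if (any(!done)) {
    idx <- which(!done)
    uc <- unique(cigar[idx])
    tab <- vapply(uc, .parse_cigar_one, c(ref = 0L, qry = 0L,
                                          lclip = 0L, rclip = 0L))
    j <- match(cigar[idx], uc)
    ref[idx] <- tab["ref", j]; qry[idx] <- tab["qry", j]
    lclip[idx] <- tab["lclip", j]; rclip[idx] <- tab["rclip", j]
  }
  data.frame(ref_width = ref, qwidth = qry, lclip = lclip, rclip = rclip)
}

# misc ------------------------------------------------------------------

## population standard deviation (exactly predictable on small fixtures)
pop_sd <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## apply substitutions at `rate` to a character vector of sequences
mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  vapply(seq, function(s) {
    n <- nchar(s)
    k <- stats::rbinom(1L, n, rate)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    repl <- vapply(ch[pos], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
    ch[pos] <- repl
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
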