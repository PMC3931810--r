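#' Splicing-regulatory element (SRE) gain/loss analysis at E+1
#'
#' An E+1 substitution can create exonic splicing silencers (ESS) or
#' destroy exonic splicing enhancers (ESE) whose windows overlap the
#' mutated position.  `scan_deltas()` counts such gains and losses for a
#' collection of motif sets and applies the positivity rule: a prediction
#' is positive when ESS gains outnumber ESS losses, or ESE losses
#' outnumber ESE gains (per element class, joined by OR).
#'
#' Scanning runs in one of two modes: `borders_kept` evaluates
#' exonic-only motif sets solely on windows lying entirely within the
#' exon, whereas `all_exonic` treats the whole sequence as exonic and
#' admits every window overlapping E+1.
#'
#' @name sre
NULL

#' Construct a motif set
#'
#' @param name set label.
#' @param element_class `"ESE"`, `"ESS"` or `"unspecified"`.
#' @param kmers character vector of fixed-length motifs (all the same
#'   width), or NULL when a weight matrix is given.
#' @param pwm optional 4 x k matrix (rows A,C,G,T) scored additively with
#'   log2(f/0.25); an occurrence is a window scoring `>= threshold`.
#' @param threshold score threshold, required with `pwm`.
#' @param applicability `"exonic_only"` (default for exonic element sets)
#'   or `"anywhere"`.
#' @return object of class `motif_set`.
#' @export
motif_set <- function(name, element_class = c("ESE", "ESS", "unspecified"),
                      kmers = NULL, pwm = NULL, threshold = NULL,
                      applicability = c("exonic_only", "anywhere")) {
  element_class <- match.arg(element_class)
  applicability <- match.arg(applicability)
  if (is.null(kmers) == is.null(pwm))
    stop("motif set '", name, "': give exactly one of kmers or pwm")
  if (!is.null(kmers)) {
    kmers <- toupper(kmers)
    if (length(unique(nchar(kmers))) != 1L)
      stop("motif set '", name, "': k-mers must all have the same length")
    width <- nchar(kmers[1])
  } else {
    stopifnot(is.matrix(pwm), nrow(pwm) == 4L, !is.null(threshold))
    rownames(pwm) <- c("A", "C", "G", "T")
    width <- ncol(pwm)
  }
  structure(list(name = name, element_class = element_class, kmers = kmers,
                 pwm = pwm, threshold = threshold,
                 applicability = applicability, width = as.integer(width)),
            class = "motif_set")
}

# does the window starting at each position of starts match the set?
motif_hits <- function(set, seq, starts) {
  if (!length(starts)) return(logical(0))
  windows <- substring(seq, starts, starts + set$width - 1L)
  if (!is.null(set$kmers)) return(windows %in% set$kmers)
  lw <- log2(pmax(set$pwm, 1e-3) / 0.25)
  vapply(windows, function(wdw) {
    idx <- match(strsplit(wdw, "")[[1]], rownames(lw))
    if (anyNA(idx)) return(FALSE)
    sum(lw[cbind(idx, seq_len(set$width))]) >= set$threshold
  }, TRUE, USE.NAMES = FALSE)
}

#' Count SRE occurrence gains and losses at the E+1 position
#'
#' @param wt_context,mut_context wild-type and mutant
#'   [acceptor_context()]s differing at most at the exon-start base.
#' @param motif_sets list of [motif_set()] objects.
#' @param mode `"borders_kept"` or `"all_exonic"` (see [sre]).
#' @return object of class `sre_delta`: the mode, a per-class data.frame
#'   of `gains`/`losses`, per-set detail, and `positive`.
#' @export
scan_deltas <- function(wt_context, mut_context, motif_sets,
                        mode = c("borders_kept", "all_exonic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(wt_context, "acceptor_context"),
            inherits(mut_context, "acceptor_context"))
  if (nchar(wt_context$seq) != nchar(mut_context$seq) ||
      wt_context$exon_start != mut_context$exon_start)
    stop("wild-type and mutant contexts must be aligned")
  diffpos <- which(strsplit(wt_context$seq, "")[[1]] !=
                   strsplit(mut_context$seq, "")[[1]])
  if (length(diffpos) > 1L)
    stop("contexts differ at ", length(diffpos),
         " positions; exactly the E+1 base may differ")
  es <- wt_context$exon_start
  n <- nchar(wt_context$seq)
  detail <- lapply(motif_sets, function(set) {
    k <- set$width
    starts <- seq.int(max(1L, es - k + 1L), min(es, n - k + 1L))
    if (mode == "borders_kept" && set$applicability == "exonic_only")
      starts <- starts[starts >= es]
    wt_hit <- motif_hits(set, wt_context$seq, starts)
    mut_hit <- motif_hits(set, mut_context$seq, starts)
    data.frame(set = set$name, class = set$element_class,
               gains = sum(!wt_hit & mut_hit),
               losses = sum(wt_hit & !mut_hit),
               stringsAsFactors = FALSE)
  })
  detail <- do.call(rbind, c(detail,
    list(data.frame(set = character(), class = character(),
                    gains = integer(), losses = integer()))))
  per_class <- do.call(rbind, lapply(c("ESE", "ESS", "unspecified"), function(cl) {
    d <- detail[detail$class == cl, , drop = FALSE]
    data.frame(class = cl, gains = sum(d$gains), losses = sum(d$losses))
  }))
  ess <- per_class[per_class$class == "ESS", ]
  ese <- per_class[per_class$class == "ESE", ]
  structure(list(mode = mode, per_class = per_class, detail = detail,
                 positive = (ess$gains > ess$losses) ||
                            (ese$losses > ese$gains)),
            class = "sre_delta")
}

#' @export
print.sre_delta <- function(x, ...) {
  cat("<sre_delta> mode=", x$mode, ", positive=", x$positive, "\n", sep = "")
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Read motif sets from a plain-text file
#'
#' Format: blocks separated by blank lines; each block starts with header
#' lines `name:`, `class:` (ESE/ESS/unspecified) and `applicability:`
#' (exonic_only/anywhere), followed by one k-mer per line.  Lines
#' starting with `#` are comments.
#'
#' @param path file path.
#' @return list of [motif_set()] objects.
#' @export
read_motif_sets <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[!startsWith(lines, "#")]
  blocks <- split(lines, cumsum(lines == ""))
  blocks <- lapply(blocks, function(b) b[b != ""])
  blocks <- blocks[vapply(blocks, length, 0L) > 0L]
  lapply(blocks, function(b) {
    hdr <- grepl("^(name|class|applicability):", b)
    fields <- strsplit(b[hdr], ":\\s*")
    vals <- vapply(fields, `[`, "", 2)
    names(vals) <- vapply(fields, `[`, "", 1)
    for (f in c("name", "class", "applicability")) if (is.na(vals[f]))
      stop("motif file '", path, "': block missing '", f, ":' header")
    motif_set(vals[["name"]], vals[["class"]], kmers = b[!hdr],
              applicability = vals[["applicability"]])
  })
}
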