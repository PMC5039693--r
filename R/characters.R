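# Character data model for the anuran tympanic middle ear (TME).
#
# Three structures per taxon, lateral to medial: tympanic membrane (TM),
# tympanic annulus (TA), columella (CO). Observed co-occurrence follows a
# strict lateral-medial dependency: a lateral structure never occurs without
# the structures medial to it. Scoring therefore uses four completion rules:
#   (1) CO absent  => TA absent and TM absent
#   (2) TA absent  => TM absent
#   (3) TM present => TA present and CO present
#   (4) TA present => CO present
# Note the asymmetry: TA absent says nothing about CO (a columella can occur
# without an annulus), so CO may legitimately stay unknown.

.STATES <- c("present", "absent", "unknown")

.norm_state <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- c("1" = "present", "0" = "absent", "?" = "unknown",
           "present" = "present", "absent" = "absent",
           "unknown" = "unknown", "na" = "unknown")[x]
  out[is.na(x) | x == ""] <- "unknown"
  unname(out)
}

#' Construct a TME structure triple
#'
#' @param taxon taxon name.
#' @param tm,ta,co state of the tympanic membrane, tympanic annulus and
#'   columella; any of `"present"/"absent"/"unknown"` or `1/0/?`.
#' @return an object of class `structure_triple`.
#' @export
structure_triple <- function(taxon, tm = "unknown", ta = "unknown",
                             co = "unknown") {
  st <- .norm_state(c(tm, ta, co))
  if (anyNA(st))
    stop("unknown state token for taxon '", taxon, "': expected one of ",
         "0/1/?/present/absent/unknown")
  structure(list(taxon = as.character(taxon),
                 tm = st[1], ta = st[2], co = st[3]),
            class = "structure_triple")
}

#' @export
print.structure_triple <- function(x, ...) {
  cat(sprintf("%s: TM=%s TA=%s CO=%s\n", x$taxon, x$tm, x$ta, x$co))
  invisible(x)
}

#' Complete a triple under the lateral-medial dependency rules
#'
#' Fills in the unique minimal completion implied by the four scoring rules.
#' Rules fire only from known states: unknowns are filled, never overridden,
#' and a field no rule forces stays as given (so `complete_triple` is
#' idempotent and monotone). Contradictory input — a known state that a rule
#' applied to another known state would flip — raises an error naming the
#' violated rule.
#'
#' @param x a `structure_triple`.
#' @return the completed `structure_triple`.
#' @export
complete_triple <- function(x) {
  stopifnot(inherits(x, "structure_triple"))
  force_state <- function(x, field, value, rule) {
    cur <- x[[field]]
    if (cur == value) return(x)
    if (cur == "unknown") {
      x[[field]] <- value
      return(x)
    }
    stop("inconsistent scoring for taxon '", x$taxon, "': ", rule,
         " forces ", toupper(field), " = ", value, " but it is scored ", cur,
         call. = FALSE)
  }
  repeat {
    before <- c(x$tm, x$ta, x$co)
    if (x$co == "absent") {
      x <- force_state(x, "ta", "absent",
                       "assumption (1) [columella absent]")
      x <- force_state(x, "tm", "absent",
                       "assumption (1) [columella absent]")
    }
    if (x$ta == "absent")
      x <- force_state(x, "tm", "absent",
                       "assumption (2) [tympanic annulus absent]")
    if (x$tm == "present") {
      x <- force_state(x, "ta", "present",
                       "assumption (3) [tympanic membrane present]")
      x <- force_state(x, "co", "present",
                       "assumption (3) [tympanic membrane present]")
    }
    if (x$ta == "present")
      x <- force_state(x, "co", "present",
                       "assumption (4) [tympanic annulus present]")
    if (identical(before, c(x$tm, x$ta, x$co))) return(x)
  }
}

#' Build a character matrix from completed triples
#'
#' @param triples list of `structure_triple` (completed or raw; raw triples
#'   are completed here), or a data frame with columns `taxon`, `tm`, `ta`,
#'   `co`.
#' @param provenance optional per-row free-text source note.
#' @return a `character_matrix`: data frame with columns `taxon`, `tm`, `ta`,
#'   `co` (all completed), plus attributes `altered` (taxa whose scores were
#'   filled in by completion) and `inconsistent` (rows rejected, with the
#'   violated rule).
#' @export
character_matrix <- function(triples, provenance = NULL) {
  if (is.data.frame(triples)) {
    names(triples) <- tolower(names(triples))
    triples <- lapply(seq_len(nrow(triples)), function(i)
      structure_triple(triples$taxon[i], triples$tm[i], triples$ta[i],
                       triples$co[i]))
  }
  taxa <- vapply(triples, `[[`, "", "taxon")
  if (anyDuplicated(taxa))
    stop("duplicate taxon names: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  altered <- character(0)
  bad <- data.frame(row = integer(0), taxon = character(0),
                    reason = character(0))
  rows <- list()
  for (i in seq_along(triples)) {
    raw <- triples[[i]]
    done <- tryCatch(complete_triple(raw), error = function(e) e)
    if (inherits(done, "error")) {
      bad <- rbind(bad, data.frame(row = i, taxon = raw$taxon,
                                   reason = conditionMessage(done)))
      next
    }
    if (!identical(c(raw$tm, raw$ta, raw$co), c(done$tm, done$ta, done$co)))
      altered <- c(altered, raw$taxon)
    rows[[length(rows) + 1L]] <- data.frame(taxon = done$taxon, tm = done$tm,
                                            ta = done$ta, co = done$co)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon = character(0), tm = character(0), ta = character(0),
               co = character(0))
  if (!is.null(provenance)) attr(out, "provenance") <- provenance
  attr(out, "altered") <- altered
  attr(out, "inconsistent") <- bad
  class(out) <- c("character_matrix", "data.frame")
  out
}

#' Read a taxon/TM/TA/CO character table from TSV
#'
#' Expects a tab-separated file with a header row naming columns `taxon`,
#' `TM`, `TA`, `CO` (case-insensitive) and state tokens in
#' `0/1/?/present/absent/unknown`. Every row is completed under the
#' dependency rules; inconsistent rows are excluded and reported in the
#' `inconsistent` attribute with their line numbers.
#'
#' @param path file path.
#' @return a `character_matrix` (see [character_matrix()]).
#' @export
read_character_table <- function(path) {
  if (!file.exists(path)) stop("character table not found: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, na.strings = NULL)
  if (nrow(df) == 0L) stop("empty character table: ", path)
  names(df) <- tolower(names(df))
  need <- c("taxon", "tm", "ta", "co")
  if (!all(need %in% names(df)))
    stop("character table must have columns taxon, TM, TA, CO; found: ",
         paste(names(df), collapse = ", "))
  ## validate tokens with line numbers (header is line 1)
  for (col in c("tm", "ta", "co")) {
    ok <- !is.na(.norm_state(df[[col]]))
    if (!all(ok))
      stop("unknown state token in column ", toupper(col), " at line(s) ",
           paste(which(!ok) + 1L, collapse = ", "))
  }
  if (anyDuplicated(df$taxon)) {
    d <- which(duplicated(df$taxon) | duplicated(df$taxon, fromLast = TRUE))
    stop("duplicate taxon at line(s) ", paste(d + 1L, collapse = ", "))
  }
  m <- character_matrix(df[need])
  bad <- attr(m, "inconsistent")
  if (nrow(bad)) bad$line <- bad$row + 1L
  attr(m, "inconsistent") <- bad
  m
}

#' Extract one structure as a binary character
#'
#' @param m a `character_matrix`.
#' @param structure one of `"TM"`, `"TA"`, `"CO"`.
#' @return named integer vector over taxa: `1` present, `0` absent, `NA`
#'   unknown (the repo-wide encoding).
#' @export
extract_binary <- function(m, structure = c("TM", "TA", "CO")) {
  stopifnot(inherits(m, "character_matrix"))
  structure <- match.arg(structure)
  st <- m[[tolower(structure)]]
  out <- ifelse(st == "present", 1L, ifelse(st == "absent", 0L, NA_integer_))
  names(out) <- m$taxon
  out
}
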