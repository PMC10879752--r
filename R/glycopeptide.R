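#' Parse glycopeptide identifiers
#'
#' Glycopeptide identifications are written `PEP{Hex;HexNAc;Fuc;NeuAc;Sulfate}`:
#' the peptide backbone (a lowercase letter is permitted at the glycosylated
#' residue, e.g. `"YnTT"`) followed by five nonnegative integer monosaccharide
#' counts in fixed positional order. `parseGlycopeptide()` maps identifier
#' strings to their components; [glycopeptideString()] is its inverse, and the
#' round trip is the identity.
#'
#' @param text character vector of identifier strings.
#' @return A `data.frame` with columns `peptide`, `Hex`, `HexNAc`, `Fuc`,
#'   `NeuAc`, `Sulfate`, one row per input.
#' @examples
#' parseGlycopeptide("YnNT{7;6;0;1;0}")
#' glycopeptideString(parseGlycopeptide(c("A{0;0;0;0;0}", "YnTT{6;5;1;2;0}")))
#' @export
parseGlycopeptide <- function(text) {
  text <- as.character(text)
  rx <- "^([A-Za-z]+)\\{([^{}]*)\\}$"
  bad <- !grepl(rx, text)
  if (any(bad))
    stop("malformed glycopeptide identifier (expected PEP{c1;c2;c3;c4;c5}): '",
         text[which(bad)[1L]], "'", call. = FALSE)
  peptide <- sub(rx, "\\1", text)
  body <- sub(rx, "\\2", text)
  parts <- strsplit(body, ";", fixed = TRUE)
  counts <- matrix(0L, nrow = length(text), ncol = 5L)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 5L)
      stop("glycan composition of '", text[i], "' must have exactly 5 counts ",
           "(Hex;HexNAc;Fuc;NeuAc;Sulfate), found ", length(p), call. = FALSE)
    ok <- grepl("^[0-9]+$", p)
    if (!all(ok))
      stop("non-integer glycan count '", p[which(!ok)[1L]], "' in '", text[i],
           "'", call. = FALSE)
    counts[i, ] <- as.integer(p)
  }
  out <- data.frame(peptide = peptide, Hex = counts[, 1L], HexNAc = counts[, 2L],
                    Fuc = counts[, 3L], NeuAc = counts[, 4L],
                    Sulfate = counts[, 5L], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Render glycopeptide identifiers
#'
#' @param x a `data.frame` as returned by [parseGlycopeptide()].
#' @return character vector of canonical `PEP{Hex;HexNAc;Fuc;NeuAc;Sulfate}`
#'   strings.
#' @rdname parseGlycopeptide
#' @export
glycopeptideString <- function(x) {
  sprintf("%s{%d;%d;%d;%d;%d}", x$peptide, x$Hex, x$HexNAc, x$Fuc,
          x$NeuAc, x$Sulfate)
}
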