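# Signed gene orders -------------------------------------------------------

#' Create a signed gene order
#'
#' A gene order is the signed left-to-right sequence of the family members
#' in one genome.  The sign records transcriptional orientation.
#'
#' @param genome genome identifier (single string).
#' @param ids character vector of gene identifiers, unique within the order.
#' @param signs integer vector of +1 / -1, recycled if length 1.
#' @return an object of class `gene_order`.
#' @examples
#' gene_order("human", c("a", "b"), c(1L, -1L))
#' @export
gene_order <- function(genome, ids = character(0), signs = integer(0)) {
  ids <- as.character(ids)
  if (length(signs) == 1L && length(ids) > 1L) signs <- rep(signs, length(ids))
  signs <- as.integer(signs)
  if (length(ids) != length(signs)) abort("ids and signs differ in length")
  if (anyDuplicated(ids)) abort("duplicate gene ids in order")
  if (length(signs) && !all(signs %in% c(-1L, 1L))) abort("signs must be +1 or -1")
  structure(list(genome = as.character(genome), ids = ids, signs = signs),
            class = "gene_order")
}

#' @export
format.gene_order <- function(x, ...) {
  paste0(x$genome, ": ", order_string(x$ids, x$signs))
}

#' @export
print.gene_order <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
length.gene_order <- function(x) length(x$ids)

order_string <- function(ids, signs) {
  if (!length(ids)) return("(empty)")
  paste(paste0(ifelse(signs > 0, "+", "-"), ids), collapse = " ")
}

#' Parse a token string such as "+a -b +c" into ids and signs
#' @keywords internal
parse_signed_tokens <- function(text) {
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(list(ids = character(0), signs = integer(0)))
  first <- substr(toks, 1, 1)
  if (!all(first %in% c("+", "-"))) {
    abort(sprintf("gene token without sign: '%s'", toks[!first %in% c("+", "-")][1]),
          class = "multidiltag_bad_orders")
  }
  list(ids = substring(toks, 2), signs = ifelse(first == "+", 1L, -1L))
}

# Signature used to deduplicate candidate ancestral orders and search states.
order_sig <- function(ids, signs) {
  paste(ifelse(signs > 0, ids, paste0("-", ids)), collapse = "\r")
}
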