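#' Resolve an atom selection expression to an index mask
#'
#' Selections use a small grammar over whitespace-separated tokens:
#'
#' * `alphacarbon` — CA atoms of protein residues
#' * `protein` — atoms in standard amino-acid residues
#' * `water` — atoms in water residues (`HOH`/`WAT`/`SOL`, ...)
#' * `name <atomname>` — atoms by exact name (e.g. `name NE1`)
#' * `resid <a>` or `resid <a>-<b>` — author residue number (range inclusive)
#' * `chain <c>` — single-character chain id
#'
#' Terms combine with `and` and `or`; `and` binds tighter. Evaluation is
#' deterministic and order-stable: the mask lists matching atom indices in
#' topology order, without duplicates. An empty mask is legal.
#'
#' @param top a [topology()].
#' @param expression selection string.
#' @return integer vector of atom indices (possibly empty).
#' @examples
#' top <- topology(1:2, c("N", "CA"), "ALA", 1, "A")
#' select_atoms(top, "alphacarbon")
#' select_atoms(top, "resid 1 and name N")
#' @export
select_atoms <- function(top, expression) {
  toks <- sel_tokenize(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- sel_parse_or(st, top)
  if (st$pos <= nrow(st$toks)) {
    sel_error(st, sprintf("unexpected token '%s'", st$toks$tok[st$pos]))
  }
  which(mask)
}

sel_tokenize <- function(expression) {
  stopifnot(is.character(expression), length(expression) == 1)
  m <- gregexpr("\\S+", expression)[[1]]
  if (m[1] == -1) {
    stop("selection parse error at position 1: empty expression",
         call. = FALSE)
  }
  data.frame(
    tok = regmatches(expression, gregexpr("\\S+", expression))[[1]],
    at = as.integer(m),
    stringsAsFactors = FALSE
  )
}

sel_error <- function(st, msg) {
  at <- if (st$pos <= nrow(st$toks)) st$toks$at[st$pos] else
    st$toks$at[nrow(st$toks)] + nchar(st$toks$tok[nrow(st$toks)])
  stop(sprintf("selection parse error at position %d: %s", at, msg),
       call. = FALSE)
}

sel_peek <- function(st) {
  if (st$pos <= nrow(st$toks)) st$toks$tok[st$pos] else NA_character_
}

sel_take <- function(st) {
  t <- sel_peek(st)
  if (is.na(t)) sel_error(st, "unexpected end of expression")
  st$pos <- st$pos + 1L
  t
}

sel_parse_or <- function(st, top) {
  acc <- sel_parse_and(st, top)
  while (identical(sel_peek(st), "or")) {
    sel_take(st)
    acc <- acc | sel_parse_and(st, top)
  }
  acc
}

sel_parse_and <- function(st, top) {
  acc <- sel_parse_factor(st, top)
  while (identical(sel_peek(st), "and")) {
    sel_take(st)
    acc <- acc & sel_parse_factor(st, top)
  }
  acc
}

sel_parse_factor <- function(st, top) {
  kw <- sel_take(st)
  switch(kw,
    alphacarbon = top$name == "CA" & top$resname %in% .protein_resnames,
    protein = top$resname %in% .protein_resnames,
    water = top$resname %in% .water_resnames,
    name = top$name == sel_take(st),
    chain = {
      c <- sel_take(st)
      if (nchar(c) != 1) sel_error_prev(st, "chain id must be one character")
      top$chain == c
    },
    resid = {
      spec <- sel_take(st)
      if (grepl("^-?[0-9]+--?[0-9]+$", spec) &&
          grepl("^-?[0-9]+", spec)) {
        parts <- regmatches(spec, regexec("^(-?[0-9]+)-(-?[0-9]+)$", spec))[[1]]
        a <- as.integer(parts[2]); b <- as.integer(parts[3])
        top$resid >= a & top$resid <= b
      } else if (grepl("^-?[0-9]+$", spec)) {
        top$resid == as.integer(spec)
      } else {
        sel_error_prev(st, sprintf("bad resid spec '%s'", spec))
      }
    },
    {
      st$pos <- st$pos - 1L
      sel_error(st, sprintf("unknown keyword '%s'", kw))
    }
  )
}

sel_error_prev <- function(st, msg) {
  st$pos <- st$pos - 1L
  sel_error(st, msg)
}
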