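## Minimal atom-selection grammar.
##
##   expr    := term ('or' term)*
##   term    := factor ('and' factor)*
##   factor  := 'not' factor | '(' expr ')' | primary
##   primary := key value+            key in {resid, resname, name, chain,
##                                            element} ; resid accepts N-M
##              | 'water' | 'protein' | 'all'
##
## Evaluation against a topology is deterministic and order-preserving:
## the result is a duplicate-free, ascending atom index vector.

sel_tokenize <- function(expr) {
  expr <- gsub("([()])", " \\1 ", expr)
  toks <- strsplit(trimws(expr), "[[:space:]]+")[[1]]
  toks[toks != ""]
}

sel_keywords <- c("resid", "resname", "name", "chain", "element")
sel_ops <- c("and", "or", "not", "(", ")")

#' Select atoms from a topology
#'
#' Evaluates an expression in the package's small selection grammar (see
#' README) against a topology. Keywords: `resid` (serials or `N-M` ranges),
#' `resname`, `name`, `chain`, `element`, plus the bare words `water`,
#' `protein`, `all`, combined with `and`, `or`, `not` and parentheses.
#'
#' @param top A [topology()].
#' @param expr Selection expression (character scalar) or an integer vector
#'   of atom indices, passed through after validation.
#' @return Ascending, duplicate-free integer vector of atom indices (1-based);
#'   may be empty.
#' @export
select_atoms <- function(top, expr) {
  if (is.numeric(expr)) {
    idx <- as.integer(expr)
    stopifnot(all(idx >= 1), all(idx <= nrow(top)))
    return(sort(unique(idx)))
  }
  toks <- sel_tokenize(expr)
  if (length(toks) == 0) stop("empty selection expression")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  fail <- function(msg) stop("selection parse error at token ", pos,
                             " ('", peek(), "'): ", msg, call. = FALSE)

  parse_primary <- function() {
    t <- take()
    lt <- tolower(t)
    if (lt == "water") return(top$resname %in% water_resnames())
    if (lt == "all") return(rep(TRUE, nrow(top)))
    if (lt == "protein") {
      hetero <- c(water_resnames(), "PO4", "ADP", "ATP", "GGP", "GLU2",
                  "MG", "MN", "NA", "CL")
      return(!(top$resname %in% hetero))
    }
    if (!(lt %in% sel_keywords)) fail("expected a keyword or bare class")
    vals <- character(0)
    while (!is.na(peek()) &&
           !(tolower(peek()) %in% c(sel_keywords, sel_ops))) {
      vals <- c(vals, take())
    }
    if (length(vals) == 0) fail(paste0("keyword '", lt, "' needs a value"))
    mask <- switch(lt,
      resid = {
        ids <- integer(0)
        for (v in vals) {
          if (grepl("^[0-9]+[-:][0-9]+$", v)) {
            ab <- as.integer(strsplit(v, "[-:]")[[1]])
            ids <- c(ids, seq.int(ab[1], ab[2]))
          } else if (grepl("^[0-9]+$", v)) {
            ids <- c(ids, as.integer(v))
          } else fail(paste0("bad resid value '", v, "'"))
        }
        top$resid %in% ids
      },
      resname = {
        vv <- toupper(vals)
        unknown <- setdiff(vv, unique(top$resname))
        if (length(unknown) > 0)
          warning("unknown residue name(s): ", paste(unknown, collapse = ", "))
        top$resname %in% vv
      },
      name = top$name %in% toupper(vals),
      chain = top$chain %in% vals,
      element = top$element %in% toupper(vals)
    )
    mask
  }

  parse_factor <- function() {
    if (is.na(peek())) fail("unexpected end of expression")
    if (tolower(peek()) == "not") { take(); return(!parse_factor()) }
    if (peek() == "(") {
      take()
      m <- parse_expr()
      if (is.na(peek()) || peek() != ")") fail("expected ')'")
      take()
      return(m)
    }
    parse_primary()
  }

  parse_term <- function() {
    m <- parse_factor()
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      m <- m & parse_factor()
    }
    m
  }

  parse_expr <- function() {
    m <- parse_term()
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      m <- m | parse_term()
    }
    m
  }

  mask <- parse_expr()
  if (!is.na(peek())) fail("trailing tokens")
  which(mask)
}

#' Truncate a residue's side chain to alanine
#'
#' Removes side-chain atoms beyond the beta carbon, renames the residue ALA,
#' and leaves every other atom (and all retained coordinates) untouched.
#' Backbone atoms N, CA, C, O (plus OXT, amide H, HA, and beta hydrogens)
#' are kept. Mimics the alanine-scan perturbation used to delete one
#' residue's noncovalent side-chain interactions.
#'
#' @param top A [topology()].
#' @param coords Coordinate matrix `n_atoms x 3` matching `top`.
#' @param resid Residue serial to mutate.
#' @param chain Chain of the residue (default: unique chain containing it).
#' @return List with elements `topology` and `coords`.
#' @export
mutate_to_alanine <- function(top, coords, resid, chain = NULL) {
  stopifnot(nrow(top) == nrow(coords))
  in_res <- top$resid == resid
  if (!is.null(chain)) in_res <- in_res & top$chain == chain
  if (!any(in_res)) stop("residue ", resid, " not found")
  resname <- unique(top$resname[in_res])
  if (length(resname) > 1) stop("residue ", resid, " is ambiguous; give chain")
  if (resname == "GLY") stop("cannot alanine-mutate GLY (no beta carbon)")
  if (resname == "ALA") return(list(topology = top, coords = coords))
  keep_names <- c("N", "CA", "C", "O", "OXT", "CB", "H", "HN", "HA",
                  "HB", "HB1", "HB2", "HB3")
  drop <- in_res & !(top$name %in% keep_names)
  out <- top[!drop, , drop = FALSE]
  sel <- out$resid == resid
  if (!is.null(chain)) sel <- sel & out$chain == chain
  out$resname[sel] <- "ALA"
  rownames(out) <- NULL
  box <- attr(top, "box")
  if (!is.null(box)) attr(out, "box") <- box
  class(out) <- c("topology", "data.frame")
  list(topology = out, coords = coords[!drop, , drop = FALSE])
}
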