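#' Nearest-neighbor RNA-RNA thermodynamic parameter set
#'
#' Loads a parameter table holding the 16 Watson-Crick dinucleotide stack
#' free energies (37 degrees C, kcal/mol), the duplex initiation penalty,
#' the per-terminal A.U closing-pair penalty, loop-destabilization penalties
#' by loop type and size, and the linear multiloop model. The bundled
#' default is the Xia et al. 1998 Watson-Crick stack set together with a
#' simplified, monotone loop table (see the package vignette for why the
#' loop model is a documented stand-in).
#'
#' @param stack_file path to a stack table (tab-separated: `stack  XY  dG`,
#'   plus `init` and `term_au` rows). Default: the bundled Xia 1998 table.
#' @param loop_file path to a loop penalty table (`loop_type  size  dG`,
#'   plus `ml_init`/`ml_branch` rows). Default: the bundled table.
#' @return an object of class `nn_params`: a list with elements `stack`
#'   (named numeric, 16 entries keyed by top-strand dinucleotide), `init`,
#'   `term_au`, `hairpin`, `bulge`, `internal` (numeric vectors indexed by
#'   loop size as names), `ml_init`, `ml_branch`, `name`.
#' @examples
#' p <- nn_params()
#' p$stack[["GC"]]
#' @export
nn_params <- function(stack_file = NULL, loop_file = NULL) {
  default <- is.null(stack_file) && is.null(loop_file)
  if (default && !is.null(.mirscan_cache$nn_default)) {
    return(.mirscan_cache$nn_default)
  }
  if (is.null(stack_file)) {
    stack_file <- system.file("extdata", "xia1998_stacks.tsv",
                              package = "mirscan", mustWork = TRUE)
  }
  if (is.null(loop_file)) {
    loop_file <- system.file("extdata", "loop_penalties.tsv",
                             package = "mirscan", mustWork = TRUE)
  }
  st <- utils::read.table(stack_file, sep = "\t", comment.char = "#",
                          col.names = c("type", "key", "dG"),
                          colClasses = c("character", "character", "numeric"))
  lp <- utils::read.table(loop_file, sep = "\t", comment.char = "#",
                          col.names = c("type", "size", "dG"),
                          colClasses = c("character", "character", "numeric"))
  stacks <- st$dG[st$type == "stack"]
  names(stacks) <- st$key[st$type == "stack"]
  pick_loop <- function(what) {
    v <- lp$dG[lp$type == what]
    names(v) <- lp$size[lp$type == what]
    v[order(as.integer(names(v)))]
  }
  obj <- structure(list(
    stack = stacks,
    init = st$dG[st$type == "init"][1L],
    term_au = st$dG[st$type == "term_au"][1L],
    hairpin = pick_loop("hairpin"),
    bulge = pick_loop("bulge"),
    internal = pick_loop("internal"),
    ml_init = lp$dG[lp$type == "ml_init"][1L],
    ml_branch = lp$dG[lp$type == "ml_branch"][1L],
    name = basename(stack_file)
  ), class = "nn_params")
  validate_nn_params(obj)
  if (default) .mirscan_cache$nn_default <- obj
  obj
}

.mirscan_cache <- new.env(parent = emptyenv())

validate_nn_params <- function(p) {
  dinucs <- as.vector(outer(RNA_BASES, RNA_BASES, paste0))
  if (!all(dinucs %in% names(p$stack))) {
    stop("parameter set must cover all 16 Watson-Crick stacks", call. = FALSE)
  }
  if (any(p$stack >= 0)) stop("all stack energies must be negative")
  hp <- p$hairpin
  if (any(hp <= 0) || any(diff(hp) < 0)) {
    stop("hairpin penalties must be positive and non-decreasing in size")
  }
  invisible(p)
}

#' @export
print.nn_params <- function(x, ...) {
  cat("<nn_params> ", x$name, "\n", sep = "")
  cat("  16 WC stacks in [", min(x$stack), ", ", max(x$stack),
      "] kcal/mol; init ", x$init, "; terminal A.U ", x$term_au, "\n", sep = "")
  cat("  loop sizes: hairpin ", length(x$hairpin), ", bulge ",
      length(x$bulge), ", internal ", length(x$internal), "\n", sep = "")
  invisible(x)
}

# Loop penalty with Jacobson-Stockmayer extrapolation past the table end.
loop_penalty <- function(params, type, size) {
  tab <- params[[type]]
  sizes <- as.integer(names(tab))
  if (size < sizes[1L]) stop("loop size below the minimum for ", type)
  if (size <= sizes[length(sizes)]) return(unname(tab[as.character(size)]))
  nmax <- sizes[length(sizes)]
  unname(tab[length(tab)]) + 1.75 * 0.6163 * log(size / nmax)
}

#' Stack free energy of a Watson-Crick paired dinucleotide
#'
#' Looks up the nearest-neighbor free energy of the stack whose top strand
#' is `top` (guide 5'->3') and whose bottom strand is the exact Watson-Crick
#' complement. Pure table lookup; total over the 16 stacks.
#'
#' @param top two-character RNA string over ACGU.
#' @param params an [nn_params()] set.
#' @return stack free energy, kcal/mol (negative).
#' @examples
#' nn_stack_dG("AA")   # the AA/UU stack
#' @export
nn_stack_dG <- function(top, params = nn_params()) {
  if (any(nchar(top) != 2L)) stop("top must be a dinucleotide", call. = FALSE)
  if (any(grepl("[^ACGU]", top))) {
    stop("non-RNA character in dinucleotide '", top, "'", call. = FALSE)
  }
  unname(params$stack[top])
}
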