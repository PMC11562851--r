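#' Read a GMT gene-set file
#'
#' Parses the MSigDB GMT dialect: one gene set per line, tab-separated as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a line are collapsed. Two pathways with identical member sets are
#' both retained under their own names (curated collections are redundant;
#' no merging is attempted).
#'
#' @param path path to a GMT file.
#' @return An object of class `pathway_collection`: a list with `sets`
#'   (named list of character member vectors) and `description` (named
#'   character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  desc <- character(length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("GMT line %d has %d field(s); at least 3 required", i, length(f)))
    }
    nm[i] <- f[1]
    desc[i] <- f[2]
    sets[[i]] <- unique(f[-(1:2)])
  }
  names(sets) <- nm
  names(desc) <- nm
  structure(list(sets = sets, description = desc), class = "pathway_collection")
}

#' Restrict a pathway collection to genes present in a network
#'
#' Members absent from the network are dropped; pathways falling below
#' `min_size` after restriction are removed. Idempotent.
#'
#' @param pc a `pathway_collection`.
#' @param net a `ppi_network`.
#' @param min_size smallest pathway retained after restriction.
#' @return the restricted `pathway_collection`; the number of removed
#'   pathways is stored in attribute `n_dropped`.
#' @export
restrict_to_network <- function(pc, net, min_size = 1) {
  stopifnot(inherits(pc, "pathway_collection"), inherits(net, "ppi_network"))
  sets <- lapply(pc$sets, function(s) s[s %in% net$nodes])
  keep <- vapply(sets, length, integer(1)) >= min_size
  .pd_msg("pathways: %d of %d retained after network restriction (min_size=%d)",
          sum(keep), length(sets), min_size)
  out <- structure(list(sets = sets[keep], description = pc$description[keep]),
                   class = "pathway_collection")
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' @export
print.pathway_collection <- function(x, ...) {
  sz <- vapply(x$sets, length, integer(1))
  cat(sprintf("<pathway_collection> %d gene sets (sizes %s-%s)\n",
              length(x$sets),
              if (length(sz)) min(sz) else NA, if (length(sz)) max(sz) else NA))
  invisible(x)
}
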