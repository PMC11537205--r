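#' Ordered marker-gating rule table
#'
#' A rule table is an ordered list of gating rules; each rule names a class,
#' a set of channels that must be called positive, and a set that must be
#' called negative. Classification is first-match-wins in table order, so
#' re-ordering rules can change outputs: the packaged default order puts
#' specific markers before lineage-generic ones.
#'
#' @param rules List of lists, each with elements \code{class} (scalar
#'   character), \code{positive} (character vector) and \code{negative}
#'   (character vector, possibly empty).
#' @return An object of class \code{rule_table}.
#' @export
rule_table <- function(rules) {
  if (!is.list(rules)) stop("`rules` must be a list of rules")
  rules <- lapply(rules, function(r) {
    if (is.null(r$class) || length(r$class) != 1L || !nzchar(r$class)) {
      stop("every rule needs a scalar non-empty `class`")
    }
    pos <- as.character(r$positive %||% character())
    neg <- as.character(r$negative %||% character())
    if (length(pos) == 0L) stop("rule for '", r$class, "' has no positive channels")
    both <- intersect(pos, neg)
    if (length(both)) {
      stop("rule for '", r$class, "' requires '", both[1L],
           "' both positive and negative")
    }
    list(class = as.character(r$class), positive = pos, negative = neg)
  })
  structure(rules, class = "rule_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rule_table <- function(x, ...) {
  cat(sprintf("<rule_table> %d rule(s), %d class(es), %d key stain(s)\n",
              length(x), count_rule_classes(x)["n_classes"],
              count_rule_classes(x)["n_key_stains"]))
  for (r in x) {
    cat(sprintf("  %-22s +[%s]%s\n", r$class, paste(r$positive, collapse = ","),
                if (length(r$negative))
                  paste0(" -[", paste(r$negative, collapse = ","), "]") else ""))
  }
  invisible(x)
}

#' Read a rule table from YAML or JSON
#'
#' The on-disk form is an ordered array of \code{{class, positive, negative}}
#' records; order is significant (first-match-wins).
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A \code{rule_table}.
#' @export
read_rule_table <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  rule_table(raw)
}

#' Write a rule table to YAML or JSON
#'
#' @param rules A \code{rule_table}.
#' @param path Destination path; format chosen by extension.
#' @return Invisibly, \code{path}.
#' @export
write_rule_table <- function(rules, path) {
  plain <- lapply(unclass(rules), function(r) {
    list(class = r$class, positive = as.list(r$positive),
         negative = as.list(r$negative))
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(plain, path)
  }
  invisible(path)
}

#' Packaged 14-class colon gating rules
#'
#' The default transcription of the colon MxIF gating scheme: 14 cell/nucleus
#' classes defined by combinations of 17 key stains (DAPI plus 16
#' class-defining markers), evaluated first-match-wins. Options mirror
#' genuinely ambiguous points of the scheme.
#'
#' @param enterocyte_operator \code{"and"} (default) requires PanCK and
#'   NaKATPase jointly positive; \code{"or"} accepts either (encoded as two
#'   adjacent rules).
#' @param double_positive_policy How CD4+CD8+ T cells resolve:
#'   \code{"first_match"} (default) lets the cascade order decide (helper T);
#'   \code{"demote_to_parent"} sends them to the generic CD3d+ T class.
#' @return A \code{rule_table}.
#' @export
default_rule_table <- function(enterocyte_operator = c("and", "or"),
                               double_positive_policy = c("first_match",
                                                          "demote_to_parent")) {
  enterocyte_operator <- match.arg(enterocyte_operator)
  double_positive_policy <- match.arg(double_positive_policy)
  path <- system.file("extdata", "rules_table1.yaml", package = "phenopatch",
                      mustWork = TRUE)
  rules <- unclass(read_rule_table(path))
  if (enterocyte_operator == "or") {
    i <- which(vapply(rules, function(r) r$class, "") == "enterocyte")
    rules <- append(
      rules[-i],
      list(list(class = "enterocyte", positive = c("DAPI", "PanCK"),
                negative = character()),
           list(class = "enterocyte", positive = c("DAPI", "NaKATPase"),
                negative = character())),
      after = i - 1L
    )
  }
  if (double_positive_policy == "demote_to_parent") {
    # an extra rule ahead of helper/cytotoxic T absorbs CD4+CD8+ doubles into
    # the generic CD3d+ T class instead of letting cascade order decide
    i <- min(which(vapply(rules, function(r) r$class, "") == "helper_t"))
    dp <- list(class = "cd3_t", positive = c("DAPI", "CD3d", "CD4", "CD8"),
               negative = character())
    rules <- append(rules, list(dp), after = i - 1L)
  }
  rule_table(rules)
}

#' Count classes and key stains in a rule table
#'
#' @param rules A \code{rule_table}.
#' @return Named integer vector \code{c(n_classes, n_key_stains)}: the number
#'   of distinct class names and of distinct channels referenced anywhere in
#'   the rules.
#' @export
count_rule_classes <- function(rules) {
  if (length(rules) == 0L) {
    return(c(n_classes = 0L, n_key_stains = 0L))
  }
  classes <- unique(vapply(rules, function(r) r$class, ""))
  stains <- unique(unlist(lapply(rules, function(r) c(r$positive, r$negative))))
  c(n_classes = length(classes), n_key_stains = length(stains))
}

#' Channels a rule table gates on
#'
#' @param rules A \code{rule_table}.
#' @return Character vector of distinct channel names, in first-use order.
#' @export
rule_channels <- function(rules) {
  unique(unlist(lapply(rules, function(r) c(r$positive, r$negative))))
}

#' Class names of a rule table, in rule order
#'
#' @param rules A \code{rule_table}.
#' @return Character vector of distinct class names.
#' @export
rule_classes <- function(rules) {
  unique(vapply(rules, function(r) r$class, ""))
}
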