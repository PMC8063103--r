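#' Tachypacing remodeling scenarios
#'
#' The eight remodeled populations are encoded as named sets of
#' multiplicative parameter scalings applied to each model's own values:
#' 1. L-type calcium current down-regulation (`GCaL` x 0.4);
#' 2. sodium-calcium exchanger up-regulation (`ImaxNCX` x 2.5);
#' 3. sodium-potassium pump down-regulation (`ImaxNaK` x 0.5);
#' 4. decreased SERCA density (`Jmaxup` x 0.7);
#' 5. increased RyR open probability (`RyR_P[0]`, `RyR_P[1]`, `RyR_P[5]`
#'    each x 2);
#' 6. decreased RyR density (`RyR_P[11]` and `NRyRs` x 0.25);
#' 7. increased calcium buffering strength (`Buff_factor` x 0.15);
#' 8. full remodeling: the union of scenarios 1-7.
#'
#' @return list of `scenario` objects (including `"control"`, the empty
#'   scenario).
#' @export
builtin_scenarios <- function() {
  sc <- function(id, name, scalings)
    new_scenario(id = id, name = name, scalings = scalings)
  s17 <- list(
    sc(1L, "ICaL down-regulation", list(GCaL = 0.4)),
    sc(2L, "INCX up-regulation", list(ImaxNCX = 2.5)),
    sc(3L, "INaK down-regulation", list(ImaxNaK = 0.5)),
    sc(4L, "Decreased Serca2a density", list(Jmaxup = 0.7)),
    sc(5L, "Increased RyR open probability",
       list(`RyR_P[0]` = 2, `RyR_P[1]` = 2, `RyR_P[5]` = 2)),
    sc(6L, "Decreased RyR density", list(`RyR_P[11]` = 0.25, NRyRs = 0.25)),
    sc(7L, "Increased calcium buffering strength", list(Buff_factor = 0.15)))
  full <- do.call(c, lapply(s17, function(s) s$scalings))
  c(list(sc("control", "Control", list())), s17,
    list(sc(8L, "Full remodeling", full)))
}

#' Construct a remodeling scenario
#'
#' @param id scenario identifier (1-8, `"control"`, or any label).
#' @param name human-readable name.
#' @param scalings named list of strictly positive multipliers; names are
#'   parameter paths (`"GCaL"`, `"Jmaxup"`, `"RyR_P[5]"`, ...).
#' @export
new_scenario <- function(id, name, scalings) {
  if (length(scalings) && any(unlist(scalings) <= 0))
    stop("scaling multipliers must be strictly positive")
  if (length(scalings) && any(duplicated(names(scalings))))
    stop("duplicate scaling path")
  structure(list(id = id, name = name, scalings = scalings),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario %s> %s\n", x$id, x$name))
  if (length(x$scalings))
    cat(paste0("  ", names(x$scalings), " x ", unlist(x$scalings),
               collapse = "\n"), "\n")
  invisible(x)
}

#' Look up a built-in scenario by id
#'
#' @param id 1-8 or `"control"`.
#' @export
get_scenario <- function(id) {
  all <- builtin_scenarios()
  hit <- Filter(function(s) identical(s$id, id) ||
                  identical(as.character(s$id), as.character(id)), all)
  if (!length(hit)) stop("unknown scenario id: ", id)
  hit[[1]]
}

# parse "RyR_P[k]" paths (zero-based index k)
.parse_path <- function(path) {
  m <- regmatches(path, regexec("^RyR_P\\[([0-9]+)\\]$", path))[[1]]
  if (length(m)) list(field = "RyR_P", index0 = as.integer(m[2]))
  else list(field = path, index0 = NA_integer_)
}

#' Apply a remodeling scenario to a parameter set
#'
#' Each targeted parameter is multiplied by its scaling on the model's own
#' (possibly sampled) value; all other parameters are returned untouched.
#' The input is not modified.
#'
#' @param params a [cell_parameters()] object.
#' @param scenario a `scenario` (or an id accepted by [get_scenario()]).
#' @export
apply_scenario <- function(params, scenario) {
  if (!inherits(scenario, "scenario")) scenario <- get_scenario(scenario)
  out <- params
  for (path in names(scenario$scalings)) {
    mult <- scenario$scalings[[path]]
    p <- .parse_path(path)
    if (identical(p$field, "RyR_P")) {
      if (p$index0 < 0 || p$index0 > 11)
        stop("RyR_P index out of range in scaling path: ", path)
      out$RyR_P[p$index0 + 1L] <- out$RyR_P[p$index0 + 1L] * mult
    } else {
      if (is.null(out[[p$field]]) || !is.numeric(out[[p$field]]))
        stop("unknown parameter in scaling path: ", path)
      out[[p$field]] <- out[[p$field]] * mult
    }
  }
  validate_cell_parameters(out)
}
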