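# Solver backend: HiGHS through a bundled Python worker (scipy.optimize.milp).
#
# All linear and mixed-integer programs in the package go through
# solve_lp_batch(). A single persistent worker process is started on demand
# and spoken to over a localhost socket with one JSON document per line, so
# that batches of many small LPs (flux variability, blocked-reaction scans,
# the brute-force oracle) cost one round trip instead of one process launch
# each. If the socket transport is unavailable the same worker script is run
# in one-shot mode per batch.

.ms_state <- new.env(parent = emptyenv())

ms_python <- function() {
  path <- Sys.which("python")
  if (!nzchar(path)) path <- Sys.which("python3")
  if (!nzchar(path)) {
    stop("no 'python' interpreter found on the PATH; the HiGHS bridge needs ",
         "python with numpy and scipy", call. = FALSE)
  }
  path
}

ms_worker_script <- function() {
  p <- system.file("python", "highs_worker.py", package = "minsubnet")
  if (!nzchar(p) || !file.exists(p)) {
    # during devtools::load_all() inst/ is mapped directly
    p <- system.file("inst", "python", "highs_worker.py", package = "minsubnet")
  }
  if (!nzchar(p) || !file.exists(p)) {
    stop("bundled solver worker script not found", call. = FALSE)
  }
  p
}

#' Is the HiGHS solver bridge available?
#'
#' Checks that a Python interpreter with `numpy` and `scipy` can be launched.
#' The result is cached for the session.
#'
#' @return `TRUE` or `FALSE`.
#' @export
highs_available <- function() {
  if (!is.null(.ms_state$available)) return(.ms_state$available)
  ok <- tryCatch({
    out <- suppressWarnings(system2(
      ms_python(), c("-c", shQuote("from scipy.optimize import milp")),
      stdout = TRUE, stderr = TRUE))
    is.null(attr(out, "status")) || attr(out, "status") == 0
  }, error = function(e) FALSE)
  .ms_state$available <- ok
  ok
}

ms_worker_start <- function() {
  portfile <- tempfile("ms_highs_port")
  logfile <- tempfile("ms_highs_log")
  system2(ms_python(), c(ms_worker_script(), portfile),
          stdout = logfile, stderr = logfile, wait = FALSE)
  t0 <- Sys.time()
  while (!file.exists(portfile)) {
    if (as.numeric(difftime(Sys.time(), t0, units = "secs")) > 20) {
      log <- if (file.exists(logfile)) readLines(logfile, warn = FALSE) else ""
      stop("solver worker failed to start: ", paste(log, collapse = "\n"),
           call. = FALSE)
    }
    Sys.sleep(0.02)
  }
  port <- as.integer(readLines(portfile, warn = FALSE)[1])
  con <- socketConnection("127.0.0.1", port = port, blocking = TRUE,
                          open = "r+", timeout = 7200)
  .ms_state$con <- con
  con
}

ms_worker_connection <- function() {
  con <- .ms_state$con
  if (!is.null(con) && isOpen(con)) return(con)
  ms_worker_start()
}

ms_worker_stop <- function() {
  con <- .ms_state$con
  if (!is.null(con)) {
    try(close(con), silent = TRUE)
    .ms_state$con <- NULL
  }
  invisible(NULL)
}

# jsonlite helpers: keep every vector an array, map NA/Inf to null
ms_json_num <- function(x) {
  if (is.null(x)) return(NULL)
  x <- as.numeric(x)
  x[!is.finite(x)] <- NA_real_
  I(x)
}

ms_problem_json <- function(p) {
  list(
    nvar = p$nvar,
    obj = ms_json_num(p$obj),
    sense = if (is.null(p$sense)) "min" else p$sense,
    lb = ms_json_num(p$lb),
    ub = ms_json_num(p$ub),
    integrality = if (is.null(p$integrality)) NULL else I(as.integer(p$integrality)),
    A = list(i = I(as.integer(p$A$i)), j = I(as.integer(p$A$j)),
             x = ms_json_num(p$A$x)),
    rlb = ms_json_num(p$rlb),
    rub = ms_json_num(p$rub),
    time_limit = p$time_limit,
    mip_gap = p$mip_gap
  )
}

ms_request <- function(problems) {
  body <- list(op = "solve_batch",
               problems = lapply(problems, ms_problem_json))
  jsonlite::toJSON(body, auto_unbox = TRUE, na = "null", digits = NA,
                   null = "null")
}

ms_parse_response <- function(txt, n_expected) {
  if (length(txt) == 0 || !nzchar(txt)) {
    stop("solver worker returned no response (worker died?)", call. = FALSE)
  }
  resp <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  sols <- resp$solutions
  if (length(sols) != n_expected) {
    stop("solver returned ", length(sols), " solutions for ", n_expected,
         " problems", call. = FALSE)
  }
  lapply(sols, function(s) {
    list(status = s$status,
         objective = if (is.null(s$objective)) NA_real_ else as.numeric(s$objective),
         x = if (is.null(s$x)) NULL else as.numeric(unlist(s$x)),
         message = s$message)
  })
}

ms_solve_oneshot <- function(req) {
  infile <- tempfile("ms_req"); outfile <- tempfile("ms_resp")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(req, infile)
  status <- system2(ms_python(), c(ms_worker_script(), "--oneshot"),
                    stdin = infile, stdout = outfile, stderr = FALSE)
  if (!identical(status, 0L)) {
    stop("solver worker subprocess failed (exit status ", status, ")",
         call. = FALSE)
  }
  readLines(outfile, warn = FALSE)[1]
}

#' Solve a batch of linear or mixed-integer programs
#'
#' Low-level entry point to the HiGHS backend. Each problem is a list with
#' elements `nvar`, `obj` (or `NULL` for pure feasibility), `sense`
#' (`"min"`/`"max"`), variable bounds `lb`/`ub` (`NA`/`Inf` mean unbounded),
#' optional 0/1 `integrality`, and row constraints given as sparse triplets
#' `A = list(i, j, x)` with row bounds `rlb`/`rub`.
#'
#' @param problems list of problem descriptions.
#' @return A list, one element per problem, each with `status`
#'   (`"optimal"`, `"infeasible"`, `"unbounded"`, `"limit"`, `"error"`),
#'   `objective` and the primal solution `x`.
#' @keywords internal
solve_lp_batch <- function(problems) {
  if (length(problems) == 0) return(list())
  req <- ms_request(problems)
  txt <- NULL
  if (!isTRUE(.ms_state$force_oneshot)) {
    txt <- tryCatch({
      con <- ms_worker_connection()
      writeLines(req, con)
      readLines(con, n = 1, warn = FALSE)
    }, error = function(e) NULL)
    if (is.null(txt) || length(txt) == 0 || !nzchar(txt[1])) {
      ms_worker_stop()
      txt <- NULL
    }
  }
  if (is.null(txt)) txt <- ms_solve_oneshot(req)
  ms_parse_response(txt[1], length(problems))
}

# Solve a single LP/MILP, returning the solution record.
solve_lp <- function(problem) solve_lp_batch(list(problem))[[1]]
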