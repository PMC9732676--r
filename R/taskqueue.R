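#' Task records
#'
#' A task is a JSON-serializable work item executed at least once by
#' interchangeable workers. Tasks must be idempotent: executing the same
#' record twice leaves storage in the same final state. Every pipeline
#' task this package plans honors that contract, which is what makes
#' lease-based at-least-once execution safe.
#'
#' @param kind operation name, dispatched through a handler registry.
#' @param payload named list of JSON-serializable arguments.
#' @param id unique id; generated when omitted.
#' @export
task_record <- function(kind, payload = list(), id = NULL) {
  if (is.null(id)) {
    id <- sprintf("%s-%s", kind,
                  paste(format(as.hexmode(sample.int(16, 16, replace = TRUE) - 1L)),
                        collapse = ""))
  }
  structure(list(id = id, kind = kind, payload = payload,
                 lease_expiry = NULL, attempts = 0L),
            class = "task_record")
}

#' Filesystem task queue
#'
#' A dependency-free queue backed by one JSON file per task in a
#' directory. Workers acquire time-based leases; an unexpired lease
#' excludes other workers (mutual exclusion through an atomic on-disk
#' lock), and an expired lease re-exposes the task, giving at-least-once
#' execution. `clock` is injectable so tests can simulate time.
#'
#' @param path queue directory (created if absent).
#' @param clock zero-argument function returning the current time in
#'   seconds (defaults to wall clock).
#' @return a `file_queue` handle.
#' @export
file_queue <- function(path, clock = function() as.numeric(Sys.time())) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  structure(list(path = path, clock = clock), class = "file_queue")
}

queue_lock <- function(queue, timeout = 10) {
  # dir.create is atomic on POSIX filesystems: the advisory lock primitive
  lockdir <- file.path(queue$path, ".lock")
  t0 <- Sys.time()
  while (!dir.create(lockdir, showWarnings = FALSE)) {
    if (as.numeric(Sys.time() - t0) > timeout) stop("queue lock timeout")
    Sys.sleep(0.01)
  }
  lockdir
}

queue_unlock <- function(lockdir) unlink(lockdir, recursive = TRUE)

with_queue_lock <- function(queue, expr) {
  lk <- queue_lock(queue)
  on.exit(queue_unlock(lk))
  expr
}

task_path <- function(queue, id) file.path(queue$path, paste0(id, ".json"))

read_task <- function(path) {
  t <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  structure(list(id = t$id, kind = t$kind, payload = t$payload,
                 lease_expiry = t$lease_expiry, attempts = as.integer(t$attempts)),
            class = "task_record")
}

write_task <- function(queue, task) {
  jsonlite::write_json(unclass(task), task_path(queue, task$id),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Queue operations
#'
#' `enqueue()` durably stores records (append-only; immediately leasable).
#' `lease()` returns a task with no unexpired lease, stamping
#' `lease_expiry = now + seconds` and incrementing its attempt count, or
#' `NULL` when nothing is leasable. `delete_task()` removes a record
#' permanently; `renew()` extends an unexpired lease (renewing an expired
#' one is an error); `purge()` empties the queue; `count_pending()`
#' reports the number of stored tasks (exact when quiescent).
#'
#' @param queue a [file_queue()].
#' @param records list of [task_record()]s.
#' @return `enqueue`: number of records stored.
#' @export
enqueue <- function(queue, records) {
  if (inherits(records, "task_record")) records <- list(records)
  with_queue_lock(queue, {
    for (t in records) write_task(queue, t)
  })
  length(records)
}

#' @rdname enqueue
#' @param seconds lease duration (> 0).
#' @export
lease <- function(queue, seconds) {
  stopifnot(seconds > 0)
  now <- queue$clock()
  with_queue_lock(queue, {
    for (f in list.files(queue$path, pattern = "\\.json$", full.names = TRUE)) {
      task <- tryCatch(read_task(f), error = function(e) NULL)
      if (is.null(task)) next
      if (!is.null(task$lease_expiry) && task$lease_expiry > now) next
      task$lease_expiry <- now + seconds
      task$attempts <- task$attempts + 1L
      write_task(queue, task)
      return(task)
    }
    NULL
  })
}

#' @rdname enqueue
#' @param id task id.
#' @export
delete_task <- function(queue, id) {
  with_queue_lock(queue, unlink(task_path(queue, id)))
  invisible(NULL)
}

#' @rdname enqueue
#' @export
renew <- function(queue, id, seconds) {
  stopifnot(seconds > 0)
  now <- queue$clock()
  with_queue_lock(queue, {
    path <- task_path(queue, id)
    if (!file.exists(path)) stop("no such task: ", id)
    task <- read_task(path)
    if (is.null(task$lease_expiry) || task$lease_expiry <= now) {
      stop("cannot renew: lease on ", id, " is not active")
    }
    task$lease_expiry <- now + seconds
    write_task(queue, task)
  })
  invisible(NULL)
}

#' @rdname enqueue
#' @export
purge <- function(queue) {
  with_queue_lock(queue, {
    unlink(list.files(queue$path, pattern = "\\.json$", full.names = TRUE))
  })
  invisible(NULL)
}

#' @rdname enqueue
#' @export
count_pending <- function(queue) {
  length(list.files(queue$path, pattern = "\\.json$"))
}

#' Worker execution loop
#'
#' Repeatedly leases a task, dispatches it by kind through `registry`
#' (a named list of `function(payload)` handlers) and deletes it on
#' success. A handler error leaves the task in place so its lease lapses
#' and the task recycles — at-least-once semantics. Polling backs off
#' exponentially while the queue is empty; with `auto_terminate = TRUE`
#' (the FileQueue default) the loop returns once the queue drains.
#'
#' @param queue a [file_queue()].
#' @param registry named list mapping task kind to handler.
#' @param lease_seconds lease duration per execution attempt.
#' @param auto_terminate return when the queue is empty.
#' @param max_iterations safety bound on loop turns.
#' @param on_error `"recycle"` (default) leaves failed tasks for re-lease;
#'   `"stop"` re-raises, for debugging.
#' @return invisibly, the number of successful executions.
#' @export
execute_loop <- function(queue, registry, lease_seconds = 60,
                         auto_terminate = TRUE, max_iterations = 100000,
                         on_error = c("recycle", "stop")) {
  on_error <- match.arg(on_error)
  executed <- 0L
  backoff <- 0.01
  for (i in seq_len(max_iterations)) {
    if (auto_terminate && count_pending(queue) == 0) break
    task <- lease(queue, lease_seconds)
    if (is.null(task)) {
      if (auto_terminate && count_pending(queue) == 0) break
      Sys.sleep(backoff)
      backoff <- min(backoff * 2, 1)
      next
    }
    backoff <- 0.01
    handler <- registry[[task$kind]]
    if (is.null(handler)) stop("no handler registered for kind: ", task$kind)
    ok <- tryCatch({
      handler(task$payload)
      TRUE
    }, error = function(e) {
      if (on_error == "stop") stop(e)
      FALSE
    })
    if (ok) {
      delete_task(queue, task$id)
      executed <- executed + 1L
    }
    # on failure the task is NOT deleted; it recycles at lease expiry
  }
  invisible(executed)
}
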