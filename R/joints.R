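#' Joint identifiers
#'
#' The assessment instruments six lower-limb joints: hip, knee and ankle,
#' bilaterally. A joint id is a string `"<side>_<joint>"`, e.g. `"left_knee"`.
#' These helpers construct and decompose joint ids and derive anatomical
#' relations (contralateral homologue, ipsilateral neighbours) used when
#' pooling reference statistics across body sides.
#'
#' @param side `"left"` or `"right"`.
#' @param joint `"hip"`, `"knee"` or `"ankle"`.
#' @return `joint_id()` returns a single string; `all_joints()` the six ids.
#' @examples
#' joint_id("left", "knee")
#' contralateral_joint("left_knee")
#' @export
joint_id <- function(side, joint) {
  side <- match.arg(side, c("left", "right"))
  joint <- match.arg(joint, c("hip", "knee", "ankle"))
  paste(side, joint, sep = "_")
}

#' @rdname joint_id
#' @export
all_joints <- function() {
  as.vector(outer(c("left", "right"), c("hip", "knee", "ankle"),
                  function(s, j) paste(s, j, sep = "_")))
}

#' @rdname joint_id
#' @param id a joint id string.
#' @export
joint_side <- function(id) {
  sub("_.*$", "", assert_joint_id(id))
}

#' @rdname joint_id
#' @export
joint_name <- function(id) {
  sub("^[^_]*_", "", assert_joint_id(id))
}

#' @rdname joint_id
#' @export
contralateral_joint <- function(id) {
  side <- joint_side(id)
  joint_id(ifelse(side == "left", "right", "left"), joint_name(id))
}

assert_joint_id <- function(id) {
  ok <- is.character(id) & id %in% all_joints()
  if (!all(ok)) {
    stop("invalid joint id(s): ", paste(unique(id[!ok]), collapse = ", "),
         " (expected one of ", paste(all_joints(), collapse = ", "), ")",
         call. = FALSE)
  }
  id
}

#' Express a joint relative to the target joint of a trial
#'
#' Reference statistics are pooled over left and right target joints by
#' mirroring: a non-target joint is identified by its joint name and by
#' whether it lies on the same (`ipsi`) or opposite (`contra`) side as the
#' target. For a left-knee trial, `"left_hip"` becomes `"ipsi_hip"` and
#' `"right_knee"` becomes `"contra_knee"`.
#'
#' @param id joint id to express relatively.
#' @param target target-joint id of the trial.
#' @return a string like `"ipsi_hip"` or `"contra_knee"`; `"target"` if
#'   `id == target`.
#' @export
relative_joint <- function(id, target) {
  assert_joint_id(id)
  assert_joint_id(target)
  if (id == target) return("target")
  rel <- ifelse(joint_side(id) == joint_side(target), "ipsi", "contra")
  paste(rel, joint_name(id), sep = "_")
}

#' Map body sides to affectedness labels
#'
#' Summary scores average joints of the more- and less-affected leg. The
#' side labelling comes from the clinical diagnosis (input metadata); it is
#' never inferred from scores. Bilateral cases still designate one side as
#' more affected.
#'
#' @param more_affected `"left"` or `"right"`.
#' @return named character vector mapping `"left"`/`"right"` to
#'   `"more_affected"`/`"less_affected"`.
#' @export
affected_side_map <- function(more_affected = c("left", "right")) {
  more_affected <- match.arg(more_affected)
  less <- ifelse(more_affected == "left", "right", "left")
  stats::setNames(c("more_affected", "less_affected"), c(more_affected, less))
}
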