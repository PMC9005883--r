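#' Convert ergometer power to pace
#'
#' On an air-braked rowing ergometer the brake torque grows with the square of
#' flywheel speed, so mechanical power grows with the cube of (virtual) boat
#' speed. The monitor's power-to-pace relation is the cube-law drag model
#' \deqn{pace = (k / P)^{1/3}}
#' with \eqn{k} the drag constant in W s\eqn{^3} m\eqn{^{-3}} (2.8 for the
#' standard Concept2 calibration). At 400 W this gives a pace of 0.1913 s/m,
#' i.e. 5.23 m/s.
#'
#' @param power Mechanical power in watts (vectorised, all > 0).
#' @param drag_constant Drag-model constant, watts at 1 m/s. Default 2.8.
#' @return Pace in seconds per metre.
#' @seealso [pace_to_speed()], [power_from_speed()], [step_distance()]
#' @examples
#' power_to_pace(350) # 0.2 s/m, i.e. 5 m/s
#' 1 / power_to_pace(400) # 5.23 m/s
#' @export
power_to_pace <- function(power, drag_constant = 2.8) {
  check_positive(power, "power")
  check_positive(drag_constant, "drag_constant")
  (drag_constant / power)^(1 / 3)
}

#' Convert pace to speed
#'
#' @param pace Pace in seconds per metre (> 0).
#' @return Speed in metres per second (the reciprocal).
#' @examples
#' pace_to_speed(0.2) # 5 m/s
#' @export
pace_to_speed <- function(pace) {
  check_positive(pace, "pace")
  1 / pace
}

#' Power required at a given speed
#'
#' Inverse of [power_to_pace()]: \eqn{P = k v^3}.
#'
#' @param speed Speed in metres per second (> 0).
#' @inheritParams power_to_pace
#' @return Power in watts.
#' @examples
#' power_from_speed(5) # 350 W
#' @export
power_from_speed <- function(speed, drag_constant = 2.8) {
  check_positive(speed, "speed")
  check_positive(drag_constant, "drag_constant")
  drag_constant * speed^3
}

#' Incremental-test step protocol
#'
#' One stage of an incremental ergometer test: a constant-power rowing bout
#' followed by a short rest for blood sampling. Speed within the bout is taken
#' as constant (the reciprocal of the pace at the step power); the rest
#' contributes no distance.
#'
#' @param power Step power in watts (> 0).
#' @param work_duration Rowing time in seconds (> 0). Default 180 s.
#' @param rest_duration Sampling rest in seconds (>= 0). Default 27 s.
#' @return A `step_protocol` list with the three fields.
#' @export
step_protocol <- function(power, work_duration = 180, rest_duration = 27) {
  check_positive(power, "power")
  check_positive(work_duration, "work_duration")
  check_non_negative(rest_duration, "rest_duration")
  structure(
    list(power = power, work_duration = work_duration,
         rest_duration = rest_duration),
    class = "step_protocol"
  )
}

#' Distance covered during one step
#'
#' \eqn{D = t_{work} / pace}: work duration divided by the pace at the step
#' power. Rest time is excluded.
#'
#' @param protocol A [step_protocol()], or a power in watts.
#' @param work_duration Rowing time in seconds; ignored when `protocol` is a
#'   `step_protocol`.
#' @inheritParams power_to_pace
#' @return Distance in metres.
#' @examples
#' step_distance(step_protocol(350, 180)) # 900 m
#' @export
step_distance <- function(protocol, work_duration = 180, drag_constant = 2.8) {
  if (inherits(protocol, "step_protocol")) {
    power <- protocol$power
    work_duration <- protocol$work_duration
  } else {
    power <- protocol
    check_positive(work_duration, "work_duration")
  }
  work_duration / power_to_pace(power, drag_constant)
}
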