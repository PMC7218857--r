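Package: imugait
Title: Wearable IMU Gait Kinematics: Calibration, Sensor Fusion, Joint
    Angles, Drift Correction and Agreement Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sagittal-plane human gait kinematics from low-cost
    wearable inertial measurement units (tri-axial gyroscope plus
    accelerometer on trunk, thighs, shanks and feet). Implements a 10-second
    static calibration (gyroscope offset removal and accelerometer norm
    normalisation with fixed scale factors), segment orientation estimation
    by a fixed-gain complementary filter and a two-state (angle, gyro-bias)
    Kalman filter initialised from the accelerometer inclination, a
    trigonometric hip/knee/ankle joint-angle computation with segment range
    conventions, regression-based drift correction (shallow neural network
    trained by Levenberg-Marquardt with early stopping, regression trees,
    epsilon-insensitive support vector regression) mapping joint angle and
    angular velocity to a reference angle, and an agreement/benchmarking
    suite (NRMSE, Pearson correlation, cross-approximate entropy, drift
    slope and ratio, turn drift increment, Bland-Altman limits of agreement,
    one-sample t-test, System Usability Scale scoring). A synthetic gait and
    IMU signal simulator generates ground-truth kinematics and raw sensor
    count streams with configurable bias, noise, drift and 180-degree turn
    events so the full pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
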