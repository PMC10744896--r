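RAW_yaw_AVG_0
RAW_pitch_AVG_0
RAW_roll_AVG_0
RAW_Leye_x_AVG_0
RAW_Leye_y_AVG_0
RAW_Reye_x_AVG_0
RAW_Reye_y_AVG_0
RAW_nose_x_AVG_0
RAW_nose_y_AVG_0
RAW_neck_x_AVG_0
RAW_neck_y_AVG_0
RAW_Lshoulder_x_AVG_0
RAW_Lshoulder_y_AVG_0
RAW_Rshoulder_x_AVG_0
RAW_Rshoulder_y_AVG_0
OFFSET_yaw_AVG_0
OFFSET_pitch_AVG_0
OFFSET_roll_AVG_0
OFFSET_Leye_x_AVG_0
OFFSET_Leye_y_AVG_0
OFFSET_Reye_x_AVG_0
OFFSET_Reye_y_AVG_0
OFFSET_nose_x_AVG_0
OFFSET_nose_y_AVG_0
OFFSET_neck_x_AVG_0
OFFSET_neck_y_AVG_0
OFFSET_Lshoulder_x_AVG_0
OFFSET_Lshoulder_y_AVG_0
OFFSET_Rshoulder_x_AVG_0
OFFSET_Rshoulder_y_AVG_0
Yaw_Normal_0
Yaw_Mild_Right_0
Yaw_Moderate_Right_0
Yaw_Severe_Right_0
Yaw_Mild_Left_0
Yaw_Moderate_Left_0
Yaw_Severe_Left_0
Pitch_Normal_0
Pitch_Mild_Right_0
Pitch_Moderate_Right_0
Pitch_Severe_Right_0
Pitch_Mild_Left_0
Pitch_Moderate_Left_0
Pitch_Severe_Left_0
Roll_Normal_0
Roll_Mild_Right_0
Roll_Moderate_Right_0
Roll_Severe_Right_0
Roll_Mild_Left_0
Roll_Moderate_Left_0
Roll_Severe_Left_0
Shoulder_Normal_0
Shoulder_Imbalance_Right_0
Shoulder_Imbalance_Left_0
Shrug_0
Leye_x_Mneck_0
Leye_y_Mneck_0
Reye_x_Mneck_0
Reye_y_Mneck_0
nose_x_Mneck_0
nose_y_Mneck_0
Lshoulder_x_Mneck_0
Lshoulder_y_Mneck_0
Rshoulder_x_Mneck_0
Rshoulder_y_Mneck_0
OFFSET_Leye_x_Mneck_0
OFFSET_Leye_y_Mneck_0
OFFSET_Reye_x_Mneck_0
OFFSET_Reye_y_Mneck_0
OFFSET_nose_x_Mneck_0
OFFSET_nose_y_Mneck_0
OFFSET_Lshoulder_x_Mneck_0
OFFSET_Lshoulder_y_Mneck_0
OFFSET_Rshoulder_x_Mneck_0
OFFSET_Rshoulder_y_Mneck_0
yaw_SD_0
pitch_SD_0
roll_SD_0
Leye_x_SD_0
Leye_y_SD_0
Reye_x_SD_0
Reye_y_SD_0
nose_x_SD_0
nose_y_SD_0
neck_x_SD_0
neck_y_SD_0
Lshoulder_x_SD_0
Lshoulder_y_SD_0
Rshoulder_x_SD_0
Rshoulder_y_SD_0
Shoulder_Diff_0
Offset_Shoulder_Diff_0
ABS_Shoulder_Diff_0
ABS_Offset_Shoulder_Diff_0
RAW_yaw_AVG_1
RAW_pitch_AVG_1
RAW_roll_AVG_1
RAW_Leye_x_AVG_1
RAW_Leye_y_AVG_1
RAW_Reye_x_AVG_1
RAW_Reye_y_AVG_1
RAW_nose_x_AVG_1
RAW_nose_y_AVG_1
RAW_neck_x_AVG_1
RAW_neck_y_AVG_1
RAW_Lshoulder_x_AVG_1
RAW_Lshoulder_y_AVG_1
RAW_Rshoulder_x_AVG_1
RAW_Rshoulder_y_AVG_1
OFFSET_yaw_AVG_1
OFFSET_pitch_AVG_1
OFFSET_roll_AVG_1
OFFSET_Leye_x_AVG_1
OFFSET_Leye_y_AVG_1
OFFSET_Reye_x_AVG_1
OFFSET_Reye_y_AVG_1
OFFSET_nose_x_AVG_1
OFFSET_nose_y_AVG_1
OFFSET_neck_x_AVG_1
OFFSET_neck_y_AVG_1
OFFSET_Lshoulder_x_AVG_1
OFFSET_Lshoulder_y_AVG_1
OFFSET_Rshoulder_x_AVG_1
OFFSET_Rshoulder_y_AVG_1
Yaw_Normal_1
Yaw_Mild_Right_1
Yaw_Moderate_Right_1
Yaw_Severe_Right_1
Yaw_Mild_Left_1
Yaw_Moderate_Left_1
Yaw_Severe_Left_1
Pitch_Normal_1
Pitch_Mild_Right_1
Pitch_Moderate_Right_1
Pitch_Severe_Right_1
Pitch_Mild_Left_1
Pitch_Moderate_Left_1
Pitch_Severe_Left_1
Roll_Normal_1
Roll_Mild_Right_1
Roll_Moderate_Right_1
Roll_Severe_Right_1
Roll_Mild_Left_1
Roll_Moderate_Left_1
Roll_Severe_Left_1
Shoulder_Normal_1
Shoulder_Imbalance_Right_1
Shoulder_Imbalance_Left_1
Shrug_1
Leye_x_Mneck_1
Leye_y_Mneck_1
Reye_x_Mneck_1
Reye_y_Mneck_1
nose_x_Mneck_1
nose_y_Mneck_1
Lshoulder_x_Mneck_1
Lshoulder_y_Mneck_1
Rshoulder_x_Mneck_1
Rshoulder_y_Mneck_1
OFFSET_Leye_x_Mneck_1
OFFSET_Leye_y_Mneck_1
OFFSET_Reye_x_Mneck_1
OFFSET_Reye_y_Mneck_1
OFFSET_nose_x_Mneck_1
OFFSET_nose_y_Mneck_1
OFFSET_Lshoulder_x_Mneck_1
OFFSET_Lshoulder_y_Mneck_1
OFFSET_Rshoulder_x_Mneck_1
OFFSET_Rshoulder_y_Mneck_1
yaw_SD_1
pitch_SD_1
roll_SD_1
Leye_x_SD_1
Leye_y_SD_1
Reye_x_SD_1
Reye_y_SD_1
nose_x_SD_1
nose_y_SD_1
neck_x_SD_1
neck_y_SD_1
Lshoulder_x_SD_1
Lshoulder_y_SD_1
Rshoulder_x_SD_1
Rshoulder_y_SD_1
Shoulder_Diff_1
Offset_Shoulder_Diff_1
ABS_Shoulder_Diff_1
ABS_Offset_Shoulder_Diff_1
RAW_yaw_AVG_2
RAW_pitch_AVG_2
RAW_roll_AVG_2
RAW_Leye_x_AVG_2
RAW_Leye_y_AVG_2
RAW_Reye_x_AVG_2
RAW_Reye_y_AVG_2
RAW_nose_x_AVG_2
RAW_nose_y_AVG_2
RAW_neck_x_AVG_2
RAW_neck_y_AVG_2
RAW_Lshoulder_x_AVG_2
RAW_Lshoulder_y_AVG_2
RAW_Rshoulder_x_AVG_2
RAW_Rshoulder_y_AVG_2
OFFSET_yaw_AVG_2
OFFSET_pitch_AVG_2
OFFSET_roll_AVG_2
OFFSET_Leye_x_AVG_2
OFFSET_Leye_y_AVG_2
OFFSET_Reye_x_AVG_2
OFFSET_Reye_y_AVG_2
OFFSET_nose_x_AVG_2
OFFSET_nose_y_AVG_2
OFFSET_neck_x_AVG_2
OFFSET_neck_y_AVG_2
OFFSET_Lshoulder_x_AVG_2
OFFSET_Lshoulder_y_AVG_2
OFFSET_Rshoulder_x_AVG_2
OFFSET_Rshoulder_y_AVG_2
Yaw_Normal_2
Yaw_Mild_Right_2
Yaw_Moderate_Right_2
Yaw_Severe_Right_2
Yaw_Mild_Left_2
Yaw_Moderate_Left_2
Yaw_Severe_Left_2
Pitch_Normal_2
Pitch_Mild_Right_2
Pitch_Moderate_Right_2
Pitch_Severe_Right_2
Pitch_Mild_Left_2
Pitch_Moderate_Left_2
Pitch_Severe_Left_2
Roll_Normal_2
Roll_Mild_Right_2
Roll_Moderate_Right_2
Roll_Severe_Right_2
Roll_Mild_Left_2
Roll_Moderate_Left_2
Roll_Severe_Left_2
Shoulder_Normal_2
Shoulder_Imbalance_Right_2
Shoulder_Imbalance_Left_2
Shrug_2
Leye_x_Mneck_2
Leye_y_Mneck_2
Reye_x_Mneck_2
Reye_y_Mneck_2
nose_x_Mneck_2
nose_y_Mneck_2
Lshoulder_x_Mneck_2
Lshoulder_y_Mneck_2
Rshoulder_x_Mneck_2
Rshoulder_y_Mneck_2
OFFSET_Leye_x_Mneck_2
OFFSET_Leye_y_Mneck_2
OFFSET_Reye_x_Mneck_2
OFFSET_Reye_y_Mneck_2
OFFSET_nose_x_Mneck_2
OFFSET_nose_y_Mneck_2
OFFSET_Lshoulder_x_Mneck_2
OFFSET_Lshoulder_y_Mneck_2
OFFSET_Rshoulder_x_Mneck_2
OFFSET_Rshoulder_y_Mneck_2
yaw_SD_2
pitch_SD_2
roll_SD_2
Leye_x_SD_2
Leye_y_SD_2
Reye_x_SD_2
Reye_y_SD_2
nose_x_SD_2
nose_y_SD_2
neck_x_SD_2
neck_y_SD_2
Lshoulder_x_SD_2
Lshoulder_y_SD_2
Rshoulder_x_SD_2
Rshoulder_y_SD_2
Shoulder_Diff_2
Offset_Shoulder_Diff_2
ABS_Shoulder_Diff_2
ABS_Offset_Shoulder_Diff_2
RAW_yaw_AVG_3
RAW_pitch_AVG_3
RAW_roll_AVG_3
RAW_Leye_x_AVG_3
RAW_Leye_y_AVG_3
RAW_Reye_x_AVG_3
RAW_Reye_y_AVG_3
RAW_nose_x_AVG_3
RAW_nose_y_AVG_3
RAW_neck_x_AVG_3
RAW_neck_y_AVG_3
RAW_Lshoulder_x_AVG_3
RAW_Lshoulder_y_AVG_3
RAW_Rshoulder_x_AVG_3
RAW_Rshoulder_y_AVG_3
OFFSET_yaw_AVG_3
OFFSET_pitch_AVG_3
OFFSET_roll_AVG_3
OFFSET_Leye_x_AVG_3
OFFSET_Leye_y_AVG_3
OFFSET_Reye_x_AVG_3
OFFSET_Reye_y_AVG_3
OFFSET_nose_x_AVG_3
OFFSET_nose_y_AVG_3
OFFSET_neck_x_AVG_3
OFFSET_neck_y_AVG_3
OFFSET_Lshoulder_x_AVG_3
OFFSET_Lshoulder_y_AVG_3
OFFSET_Rshoulder_x_AVG_3
OFFSET_Rshoulder_y_AVG_3
Yaw_Normal_3
Yaw_Mild_Right_3
Yaw_Moderate_Right_3
Yaw_Severe_Right_3
Yaw_Mild_Left_3
Yaw_Moderate_Left_3
Yaw_Severe_Left_3
Pitch_Normal_3
Pitch_Mild_Right_3
Pitch_Moderate_Right_3
Pitch_Severe_Right_3
Pitch_Mild_Left_3
Pitch_Moderate_Left_3
Pitch_Severe_Left_3
Roll_Normal_3
Roll_Mild_Right_3
Roll_Moderate_Right_3
Roll_Severe_Right_3
Roll_Mild_Left_3
Roll_Moderate_Left_3
Roll_Severe_Left_3
Shoulder_Normal_3
Shoulder_Imbalance_Right_3
Shoulder_Imbalance_Left_3
Shrug_3
Leye_x_Mneck_3
Leye_y_Mneck_3
Reye_x_Mneck_3
Reye_y_Mneck_3
nose_x_Mneck_3
nose_y_Mneck_3
Lshoulder_x_Mneck_3
Lshoulder_y_Mneck_3
Rshoulder_x_Mneck_3
Rshoulder_y_Mneck_3
OFFSET_Leye_x_Mneck_3
OFFSET_Leye_y_Mneck_3
OFFSET_Reye_x_Mneck_3
OFFSET_Reye_y_Mneck_3
OFFSET_nose_x_Mneck_3
OFFSET_nose_y_Mneck_3
OFFSET_Lshoulder_x_Mneck_3
OFFSET_Lshoulder_y_Mneck_3
OFFSET_Rshoulder_x_Mneck_3
OFFSET_Rshoulder_y_Mneck_3
yaw_SD_3
pitch_SD_3
roll_SD_3
Leye_x_SD_3
Leye_y_SD_3
Reye_x_SD_3
Reye_y_SD_3
nose_x_SD_3
nose_y_SD_3
neck_x_SD_3
neck_y_SD_3
Lshoulder_x_SD_3
Lshoulder_y_SD_3
Rshoulder_x_SD_3
Rshoulder_y_SD_3
Shoulder_Diff_3
Offset_Shoulder_Diff_3
ABS_Shoulder_Diff_3
ABS_Offset_Shoulder_Diff_3
gender
age
height
weight
bmi
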