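"name","category","unit"
"total_deviation_straight_line","mouse_movement","percent_screen_height"
"net_deviation_straight_line","mouse_movement","percent_screen_height"
"maximum_deviation_straight_line","mouse_movement","percent_screen_height"
"average_absolute_deviation_straight_line","mouse_movement","percent_screen_height"
"mean_deviation_straight_line","mouse_movement","fraction_screen_height"
"maximum_pixel_deviation_straight_line","mouse_movement","pixels"
"deviation_sd_straight_line","mouse_movement","pixels"
"time_to_trace_a_straight_line","mouse_movement","seconds"
"time_to_trace_a_straight_line_normalized","mouse_movement","seconds_per_pixel"
"points_inside_straight_line","mouse_movement","count"
"mean_speed_straight_line","mouse_movement","pixels_per_second"
"max_speed_straight_line","mouse_movement","pixels_per_second"
"speed_sd_straight_line","mouse_movement","pixels_per_second"
"path_length_straight_line","mouse_movement","pixels"
"mean_abs_acceleration_straight_line","mouse_movement","pixels_per_second_squared"
"direction_changes_straight_line","mouse_movement","count"
"total_deviation_sine_wave","mouse_movement","percent_screen_height"
"net_deviation_sine_wave","mouse_movement","percent_screen_height"
"maximum_deviation_sine_wave","mouse_movement","percent_screen_height"
"average_absolute_deviation_sine_wave","mouse_movement","percent_screen_height"
"mean_deviation_sine_wave","mouse_movement","fraction_screen_height"
"maximum_pixel_deviation_sine_wave","mouse_movement","pixels"
"deviation_sd_sine_wave","mouse_movement","pixels"
"time_to_trace_the_sine_wave","mouse_movement","seconds"
"time_to_trace_the_sine_wave_normalized","mouse_movement","seconds_per_pixel"
"points_inside_sine_wave","mouse_movement","count"
"mean_speed_sine_wave","mouse_movement","pixels_per_second"
"max_speed_sine_wave","mouse_movement","pixels_per_second"
"speed_sd_sine_wave","mouse_movement","pixels_per_second"
"path_length_sine_wave","mouse_movement","pixels"
"mean_abs_acceleration_sine_wave","mouse_movement","pixels_per_second_squared"
"direction_changes_sine_wave","mouse_movement","count"
"total_deviation_spiral","mouse_movement","percent_screen_height"
"net_deviation_spiral","mouse_movement","percent_screen_height"
"maximum_deviation_spiral","mouse_movement","percent_screen_height"
"average_absolute_deviation_spiral","mouse_movement","percent_screen_height"
"mean_deviation_spiral","mouse_movement","fraction_screen_height"
"maximum_pixel_deviation_spiral","mouse_movement","pixels"
"deviation_sd_spiral","mouse_movement","pixels"
"time_to_trace_a_spiral","mouse_movement","seconds"
"time_to_trace_the_spiral_normalized","mouse_movement","seconds_per_pixel"
"points_inside_spiral","mouse_movement","count"
"mean_speed_spiral","mouse_movement","pixels_per_second"
"max_speed_spiral","mouse_movement","pixels_per_second"
"speed_sd_spiral","mouse_movement","pixels_per_second"
"path_length_spiral","mouse_movement","pixels"
"mean_abs_acceleration_spiral","mouse_movement","pixels_per_second_squared"
"direction_changes_spiral","mouse_movement","count"
"average_tracing_time_for_all_tasks","mouse_movement","seconds"
"average_points_inside_all_lines","mouse_movement","count"
"total_click_time_for_all_tests","mouse_click","seconds"
"total_click_reaction_time","mouse_click","seconds"
"click_hit_rate","mouse_click","ratio"
"average_click_time","mouse_click","seconds"
"click_distance_error_mean","mouse_click","pixels"
"click_time_sd","mouse_click","seconds"
"average_response_time_constant_key","keyboard","seconds"
"response_time_sd_constant_key","keyboard","seconds"
"correct_press_count_constant_key","keyboard","count"
"false_press_ratio_constant_key","keyboard","ratio"
"correct_the_press_rate_constant_key","keyboard","presses_per_second"
"average_response_time_two_letter_key","keyboard","seconds"
"response_time_sd_two_letter_key","keyboard","seconds"
"correct_press_count_two_letter_key","keyboard","count"
"false_press_ratio_two_letter_key","keyboard","ratio"
"correct_press_rate_two_letter_key","keyboard","presses_per_second"
"average_response_time_random_key","keyboard","seconds"
"response_time_sd_random_key","keyboard","seconds"
"correct_press_count_random_key","keyboard","count"
"false_press_ratio_random_key","keyboard","ratio"
"correct_press_rate_random_key","keyboard","presses_per_second"
"average_false_presses_all_tests","keyboard","count"
"average_response_time_all_tests","keyboard","seconds"
"memory_max_sequence_length","memory","count"
"memory_incorrect_trials","memory","count"
"sex","demographic","categorical"
"race_binary","demographic","categorical"
"device","demographic","categorical"
"hand","demographic","categorical"
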