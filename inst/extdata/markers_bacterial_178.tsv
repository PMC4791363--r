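marker
BHG001
BHG002
BHG003
BHG004
BHG005
BHG006
BHG007
BHG008
BHG009
BHG010
BHG011
BHG012
BHG013
BHG014
BHG015
BHG016
BHG017
BHG018
BHG019
BHG020
BHG021
BHG022
BHG023
BHG024
BHG025
BHG026
BHG027
BHG028
BHG029
BHG030
BHG031
BHG032
BHG033
BHG034
BHG035
BHG036
BHG037
BHG038
BHG039
BHG040
BHG041
BHG042
BHG043
BHG044
BHG045
BHG046
BHG047
BHG048
BHG049
BHG050
BHG051
BHG052
BHG053
BHG054
BHG055
BHG056
BHG057
BHG058
BHG059
BHG060
BHG061
BHG062
BHG063
BHG064
BHG065
BHG066
BHG067
BHG068
BHG069
BHG070
BHG071
BHG072
BHG073
BHG074
BHG075
BHG076
BHG077
BHG078
BHG079
BHG080
BHG081
BHG082
BHG083
BHG084
BHG085
BHG086
BHG087
BHG088
BHG089
BHG090
BHG091
BHG092
BHG093
BHG094
BHG095
BHG096
BHG097
BHG098
BHG099
BHG100
BHG101
BHG102
BHG103
BHG104
BHG105
BHG106
BHG107
BHG108
BHG109
BHG110
BHG111
BHG112
BHG113
BHG114
BHG115
BHG116
BHG117
BHG118
BHG119
BHG120
BHG121
BHG122
BHG123
BHG124
BHG125
BHG126
BHG127
BHG128
BHG129
BHG130
BHG131
BHG132
BHG133
BHG134
BHG135
BHG136
BHG137
BHG138
BHG139
BHG140
BHG141
BHG142
BHG143
BHG144
BHG145
BHG146
BHG147
BHG148
BHG149
BHG150
BHG151
BHG152
BHG153
BHG154
BHG155
BHG156
BHG157
BHG158
BHG159
BHG160
BHG161
BHG162
BHG163
BHG164
BHG165
BHG166
BHG167
BHG168
BHG169
BHG170
BHG171
BHG172
BHG173
BHG174
BHG175
BHG176
BHG177
BHG178
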