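chr1:121
chr1:122
chr1:123
chr1:124
chr1:125
chr1:126
chr1:127
chr1:249
chr2:92
chr2:93
chr2:94
chr2:243
chr3:90
chr3:91
chr3:92
chr3:198
chr4:49
chr4:50
chr4:51
chr4:191
chr5:46
chr5:47
chr5:48
chr5:180
chr6:58
chr6:59
chr6:60
chr6:171
chr7:58
chr7:59
chr7:60
chr7:159
chr8:43
chr8:44
chr8:45
chr8:146
chr9:47
chr9:48
chr9:49
chr9:50
chr9:51
chr9:52
chr9:53
chr9:54
chr9:55
chr9:56
chr9:57
chr9:58
chr9:59
chr9:60
chr9:61
chr9:62
chr9:63
chr9:64
chr9:141
chr10:39
chr10:40
chr10:41
chr10:135
chr11:51
chr11:52
chr11:53
chr11:135
chr12:34
chr12:35
chr12:36
chr12:133
chr13:0
chr13:1
chr13:2
chr13:3
chr13:4
chr13:5
chr13:6
chr13:7
chr13:8
chr13:9
chr13:10
chr13:11
chr13:12
chr13:13
chr13:14
chr13:15
chr13:16
chr13:17
chr13:18
chr13:115
chr14:0
chr14:1
chr14:2
chr14:3
chr14:4
chr14:5
chr14:6
chr14:7
chr14:8
chr14:9
chr14:10
chr14:11
chr14:12
chr14:13
chr14:14
chr14:15
chr14:16
chr14:17
chr14:18
chr14:107
chr15:0
chr15:1
chr15:2
chr15:3
chr15:4
chr15:5
chr15:6
chr15:7
chr15:8
chr15:9
chr15:10
chr15:11
chr15:12
chr15:13
chr15:14
chr15:15
chr15:16
chr15:17
chr15:18
chr15:19
chr15:102
chr16:35
chr16:36
chr16:37
chr16:38
chr16:39
chr16:40
chr16:41
chr16:42
chr16:43
chr16:44
chr16:45
chr16:90
chr17:22
chr17:23
chr17:24
chr17:81
chr18:15
chr18:16
chr18:17
chr18:78
chr19:24
chr19:25
chr19:26
chr19:59
chr20:26
chr20:27
chr20:28
chr20:63
chr21:0
chr21:1
chr21:2
chr21:3
chr21:4
chr21:5
chr21:6
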