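-30
-29
10
35
8
25
-19
32
-63
-91
-46
-104
-149
-86
-129
-125
-81
-118
-71
-61
-4
-22
19
-10
4
-65
-76
-39
-43
-14
-38
-35
-34
-33
-60
-72
-44
-72
-45
-55
-86
-30
-17
8
-44
-33
33
-35
18
39
-23
7
72
23
-13
-35
-40
-49
-86
-86
-113
-55
-56
-40
-105
-64
-71
-41
-21
-57
-30
-8
-34
-48
23
23
41
7
-1
-12
30
-6
-87
-59
-2
0
57
114
94
30
19
25
30
33
61
46
-12
-34
-64
-5
21
17
-11
-27
-4
4
19
33
18
-8
3
-46
-2
-4
-20
40
67
60
26
45
49
34
11
21
59
111
69
31
130
73
102
85
47
37
85
36
-11
2
29
49
33
37
-59
36
42
13
-16
-24
-5
34
19
14
-8
15
27
48
12
77
63
81
109
32
24
-35
24
42
39
79
92
85
35
11
-29
-8
-42
-42
-14
-43
13
44
29
-2
57
17
96
76
65
82
86
74
85
49
24
63
62
-7
-32
-52
13
-15
-23
-2
7
14
-8
-24
52
40
78
84
56
31
53
25
2
14
-0
5
82
65
33
9
41
47
8
7
3
42
-8
36
20
54
120
97
67
61
60
16
15
12
40
37
42
37
118
46
75
103
82
34
75
49
6
-32
-28
6
-23
-16
21
27
-1
-10
16
40
4
2
105
82
98
36
82
107
64
62
7
-12
30
-32
-22
-65
-44
-36
-23
-43
-74
-13
-44
-14
2
-41
-28
15
22
-8
-46
-14
14
38
34
37
-30
4
13
-108
-68
-65
20
41
70
9
-63
-27
-96
-62
-40
51
-35
0
-64
-45
9
-36
-53
-94
8
13
-12
-57
-97
-62
-70
-62
-32
-44
-15
-6
-28
-30
-19
-39
6
33
11
2
-26
11
64
82
47
60
71
69
60
61
38
3
36
71
39
65
97
112
77
22
24
45
-46
-17
-82
-51
-51
-42
-36
-30
30
0
45
54
12
74
47
-38
-23
-35
-16
-24
-64
-115
-84
-45
-57
26
-32
-4
1
-19
-65
-69
-30
9
31
73
-4
26
52
-61
-46
-34
-69
-3
-25
-39
-7
-32
-11
-62
-31
-39
-66
-57
-24
-64
-20
-13
-9
6
-41
-31
-16
-47
-46
19
35
-4
4
-7
30
-10
-27
40
3
33
11
5
14
-1
30
53
58
63
-6
-40
-7
-40
-26
13
5
-15
-31
-33
-99
-63
-115
-22
-80
-78
-60
-49
-55
-6
-1
-33
-42
8
-3
43
29
-25
-31
-81
-87
-57
-109
-96
-16
-99
-104
-66
-45
-33
-1
-61
-41
-43
-16
-6
17
98
28
45
23
4
-2
1
-7
47
66
46
22
-51
25
12
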