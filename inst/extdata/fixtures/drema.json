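{
  "study_id": "drema",
  "study_name": "drema: dream wellbeing program",
  "instructions": "<p>Welcome to <b>drema</b>. Complete each weekly module when it becomes available.</p>",
  "banner_url": "https://example.org/drema/banner.png",
  "support_email": "drema@example.org",
  "support_url": "https://example.org/drema",
  "ethics_statement": "Approved by the example institutional review board.",
  "post_url": "https://example.org/drema/post.php",
  "cache_media": true,
  "conditions": ["all"],
  "modules": [
    {
      "id": "week1_unwind",
      "type": "survey",
      "name": "Week 1: Unwind",
      "condition": "*",
      "schedule": {
        "times": ["19:00"],
        "start_offset_days": 0,
        "duration_days": 7,
        "random": false,
        "random_offset_minutes": 0,
        "sticky": false,
        "timeout": false,
        "timeout_minutes": 0,
        "alert_title": "Week 1: Unwind",
        "alert_message": "Your evening unwind session is ready"
      },
      "graph": {
        "display": true,
        "variable": "tension",
        "title": "Tension",
        "blurb": "Your tension ratings this week",
        "type": "line",
        "max_points": 7
      },
      "shuffle_sections": false,
      "sections": [
        {
          "name": "Unwind",
          "shuffle": false,
          "elements": [
            {
              "id": "scene",
              "type": "media",
              "subtype": "image",
              "src": "https://example.org/drema/calm.jpg",
              "text": "A calming scene"
            },
            {
              "id": "intro",
              "type": "instruction",
              "text": "<p>Take a moment to <i>unwind</i> before bed.</p>"
            },
            {
              "id": "activities",
              "type": "checkbox",
              "text": "Which of these did you do today?",
              "required": true,
              "options": ["exercise", "reading", "meditation", "screen time"]
            },
            {
              "id": "tension",
              "type": "slider",
              "text": "How tense do you feel right now?",
              "required": true,
              "min": 0,
              "max": 10,
              "hint_left": "relaxed",
              "hint_right": "very tense"
            },
            {
              "id": "unwind_video",
              "type": "media",
              "subtype": "video",
              "src": "https://example.org/drema/unwind.mp4",
              "thumb": "https://example.org/drema/unwind.jpg",
              "text": "Tonight's unwind video"
            }
          ]
        }
      ]
    }
  ]
}
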